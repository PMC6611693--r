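# Default English stop word list (function words common in patent prose).
# One term per line; '#' lines are comments.
a
about
above
after
again
against
all
also
an
and
any
are
as
at
be
because
been
before
being
below
between
both
but
by
can
cannot
comprises
comprising
could
did
do
does
doing
down
during
each
few
for
from
further
had
has
have
having
he
her
here
hers
him
his
how
i
if
in
into
is
it
its
itself
may
me
method
more
most
my
no
nor
not
of
off
on
once
one
only
or
other
our
out
over
own
said
same
she
should
so
some
such
than
that
the
their
theirs
them
then
there
these
they
this
those
through
to
too
under
until
up
very
was
we
were
what
when
where
wherein
which
while
who
whom
why
will
with
would
you
your
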