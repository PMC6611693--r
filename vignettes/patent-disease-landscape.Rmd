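---
title: "Mining the disease landscape of a patent corpus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining the disease landscape of a patent corpus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(patentscape)
```

patentscape implements a portfolio-level analysis of biomedical patenting:
which diseases granted patents reach, how that coverage moves over time,
how patent activity (together with publications and clinical trials)
aligns with the burden each disease imposes, and what latent technological
topics the disease-specific subcorpora contain. This vignette documents
the models, the tunable parameters and the design decisions, and is
explicit about what the synthetic-data experiments do and do not show.

## Pipeline overview

Five stages, each behind its own function surface:

1. **Filter** (`filter_corpus`): keep documents granted inside a date
   window that carry at least one USPC or CPC classification code matching
   an allowlist. The code list is *configuration*, not algorithm: real
   analyses supply their own curated list; the packaged default
   (`default_code_allowlist`) is an illustrative set of medical-technology
   prefixes so examples run out of the box. Matching defaults to prefix
   mode because CPC codes carry hierarchical subgroup suffixes
   (`A61K31/00` should match an `A61K` entry). The window is inclusive on
   both ends, and "publication date" is read as the grant date field.
2. **Annotate** (`annotate_corpus`): a deterministic dictionary recognizer
   finds disease mentions and maps them to root PheCodes.
3. **Coverage** (`coverage`): per-year share of disease-mentioning
   documents that mention each disease.
4. **Indices** (`roi`, `phi`, `vif_audit`): normalized-share comparisons of
   burden against research resources.
5. **Topics** (`fit_dtm`, `select_topic_number`): a dynamic topic model
   over calendar-year slices.

`run_pipeline` chains the stages from one declarative YAML config, writes
every table as CSV/TSV, and records a manifest (config snapshot, row
counts, warnings, failed stage if any) even on partial failure. All
randomness flows from seeds named in the config.

## Concept recognition and PheCode rollup

Production concept recognizers for biomedical text are statistical black
boxes; this package instead uses a transparent recognizer so that every
downstream number is reproducible from inputs that are plain files: a
lexicon of surface terms mapped to concept identifiers (CUIs), matched
greedily left-to-right, longest match first, case-insensitively, on token
boundaries, over title, abstract and claims (weighted equally; the three
sections are simply unioned). Overlapping shorter matches are suppressed,
so mentions never overlap in token space. A UMLS-derived lexicon can be
dropped in without code changes.

Each CUI rolls up through CUI → ICD-9-CM → PheCode → root PheCode tables.
Root PheCodes - the ~700 top-level phenotype groupings clinicians use -
are the disease unit everywhere. A rollup is *definitive* when it lands on
exactly one root (one-to-one or many-to-one) and *ambiguous* when it
diverges; `mapping_audit` reports the definitive percentage over mapped
CUIs. The default policy keeps all candidate roots of an ambiguous mention
(`ambiguity_policy = "all"`), because real mapping tables are
overwhelmingly definitive and the ambiguity-induced error is small and
bounded; `"drop"` exists for sensitivity analysis. An optional
ICD-10-CM → ICD-9-CM bridge (`bridge_icd10`) supports claims tables coded
in ICD-10-CM after the 2015 switch.

## Coverage

Coverage of disease *d* in year *t* is the number of documents mentioning
*d* divided by the number of documents mentioning *any* disease that year.
The denominator wording is genuinely open - "all disease-mentioning
documents" versus "all biomedical documents" - so the first reading is the
default (it makes coverage behave as a share, with single-disease coverage
never exceeding 1) and the second is available via
`coverage(..., denominator = "all_documents")`. Counting is
document-level: a document mentioning a disease ten times counts once.
Because documents can mention several diseases, per-year coverages can sum
to more than 1; they sum to exactly 1 only when every document mentions
exactly one disease, which the synthetic generator can force and the tests
exploit.

## ROI and PHI

Raw yearly measures $Y_{nd}(t)$ - burden as treatment cost per million
people, and publication, clinical-trial and patent counts as resources -
are incommensurable and inflate over time, so each is normalized to a
within-measure, within-year share:

$$X_{nd}(t) = \frac{Y_{nd}(t)}{\sum_{d'} Y_{nd'}(t)},$$

which is invariant to any positive rescaling of a measure-year (the
inflation-proofing that motivates normalization). The three resource
shares combine into $R_d(t) = \sum_{n \in \{r,c,p\}} w_n X_{nd}(t)$ with
configurable weights defaulting to equal thirds.

The **Research Opportunity Index** is the signed fold-imbalance between a
disease's burden share and its resource share. With
$\rho_d(t) = X_{bd}(t)/R_d(t)$:

$$\mathrm{ROI}_d(t) = \begin{cases} \rho_d(t) & \rho_d(t) \ge 1
\text{ (understudied, positive)}\\ -1/\rho_d(t) & \rho_d(t) < 1
\text{ (overstudied, negative)} \end{cases}$$

so $|\mathrm{ROI}| \ge 1$ always, $+1$ is exact alignment, and magnitude
reads as "fold": $-2$ means resources double the burden share. The
**Public Health Index** summarizes a year across all diseases as the total
variation distance between the burden-share distribution and the
resource-share distribution,
$\mathrm{PHI}(t) = \tfrac12 \sum_d |X_{bd}(t) - R_d(t)| \in [0,1]$, zero
exactly at perfect alignment, and smaller meaning better-aligned
portfolios.

These functional forms are a design decision of this package: they were
chosen as the simplest forms satisfying every property the index layer
must have - the stated sign convention, fold-style magnitudes, a
year-comparable $[0,1]$ misalignment scalar, and PHI never increasing
under any transfer of resource share toward the burden distribution (a
Pigou–Dalton-type monotonicity the tests verify). Both live behind a
single strategy point (`roi`, `phi`), so an alternative published form can
be substituted without touching callers. Zero shares produce explicit
sentinels (`"overstudied-unbounded"`, `"understudied-unbounded"`,
`"undefined"`) rather than infinities, keeping tabular exports
well-defined.

Before index analysis, `vif_audit` checks that the four measures are not
collinear: each measure's cross-disease share vector is regressed on the
other three (least squares with intercept, observations pooled over years
by default, per-year on request - the pooling choice is itself a
documented default, not a derived fact) and $\mathrm{VIF} = 1/(1-R^2)$ is
reported.

## Dynamic topic model

Disease-specific subcorpora are preprocessed in a fixed order: (1)
multiword concept mentions are replaced by their CUI token, so compounds
like "type 2 diabetes" survive as single vocabulary items; (2)
tokenization on non-alphanumeric boundaries; (3) lowercasing (CUI tokens
exempt); (4) stop-word removal; (5) lemmatization. Lemmatization is a
deterministic ordered suffix-rule table (packaged, swappable) rather than
a statistical lemmatizer - reproducibility is worth more here than
linguistic finesse. Documents left empty are dropped with a logged count.
The bag-of-words matrix is sliced by calendar year.

The model: each topic $k$ has per-slice natural parameters
$\eta_{tk} \in \mathbb{R}^V$ with $\beta_{tk} = \mathrm{softmax}(\eta_{tk})$,
chained by a Gaussian random walk
$\eta_{tk} \sim \mathcal{N}(\eta_{t-1,k},\, \sigma I)$; documents in slice
$t$ draw topic proportions $\theta_d$ governed by concentration $\alpha$
and words from the mixture $\sum_k \theta_{dk}\beta_{tk}$. Defaults
$\alpha = 0.01$ (documents concentrate on few topics), $\sigma = 0.005$
(slow topic evolution), $K = 10$ with per-disease overrides. $\sigma$
chains topic parameters only; document-level concentration does not drift.

Inference is a penalized EM written for this package: the E-step computes
expected topic-word counts and updates $\theta_{dk} \propto N_{dk} + \alpha$
(a MAP step); the M-step takes up to three gradient steps on the
chain-penalized likelihood of $\eta$ with backtracking line search, which
guarantees the recorded objective (penalized log posterior) never
decreases - an invariant the tests assert to $10^{-6}$ per token. At
$\sigma = 0$ the slices are tied and the M-step is the closed-form pooled
estimate, smoothed with a $10^{-6}$ pseudo-count so $\beta$ stays strictly
positive; for $\sigma > 0$ positivity comes from the softmax itself.
Identical data, parameters and seed give bitwise-identical fits.
Convergence is declared when the objective moves less than `tol` per
token; a fit that exhausts `n_iter` is returned with `converged = FALSE`
rather than an error. This is deliberately *not* a reimplementation of the
variational Kalman-filter inference of the original dynamic topic model;
the contract is the model family and its invariants (normalization,
seed-determinism, $\sigma$-controlled drift), which is what the analysis
layer and the recovery tests consume.

Topic quality uses UMass coherence: for a topic's top $n$ terms ordered by
probability, $\sum_{i<j} \log\frac{D(w_i,w_j)+1}{D(w_j)}$ with $D(\cdot)$
document (co-)occurrence counts from the modeled corpus; per-slice scores
are averaged with equal weights, then averaged over topics. The variant
choice (document co-occurrence rather than sliding-window) is a config
point; the formula is fixed for reproducibility. A zero denominator (a top
term absent from the matrix) is guarded to 1, since the $+1$ smooths only
the joint count. `select_topic_number` fits a grid of candidate $K$
(optionally several seeds each, averaging), returns the coherence-maximal
$K$, and breaks ties toward the smaller model.

## The synthetic generator, and what passing tests mean

`simulate_study` writes a complete study - corpus, lexicon, mapping
tables, measure tables - as real files in the external formats, with the
planted parameters exported alongside, so every stage has a
parameter-recovery test that also exercises the I/O code. The layers:

- **Corpus**: filler tokens drawn from planted per-slice topic
  distributions (disjoint vocabulary blocks with a Zipf profile per topic;
  one topic per document; optional linear keyword ramp across slices),
  disease surface terms inserted at token boundaries with per-disease
  Bernoulli probabilities, and filter bait (off-list codes, out-of-window
  dates) for the non-biomedical remainder.
- **Mappings**: a configurable fraction of CUIs wired to two roots through
  divergent ICD-9 codes; the rest one-to-one.
- **Measures**: per-year shares solved so that the burden share equals the
  planted fold times the resource share with both distributions
  normalizing ($R_d \propto e^{-c f_d}$ with $c$ from a one-dimensional
  root find; patterns whose folds do not straddle 1 are rejected as
  infeasible). Counts get Poisson noise; costs can take multiplicative
  log-normal noise; a spread option decorrelates the three resource
  measures without moving their equal-weight composite.

Defaults define the study conditions used throughout the tests: the demo
preset is 3 years × 200 documents/year × 8 diseases × 3 planted topics
with folds (3, 2, 1, 0.5), which runs end-to-end in seconds; recovery
experiments use 5,000-document corpora for filter statistics, 10,000-CUI
bundles for the mapping audit, per-measure totals of $10^5$ for
noise-recovery, and 15-120 documents per year for topic experiments.
These sizes were chosen as the smallest at which the binomial/multinomial
error bands are tight enough to be informative.

What passing recovery tests show: the implementation computes what it
claims - planted fractions, incidences, folds, topics and drift come back
within the stated statistical error, exactly where no noise is planted.
What they do not show: performance on real patent text. The generator's
documents have no legalese, no vocabulary burstiness, no OCR noise, no
lexicon gaps, and its planted topics are far better separated than real
technological themes; mapping tables are far smaller than UMLS. Results on
real corpora depend on the quality of the supplied lexicon, code
allowlist and mapping tables in ways the synthetic experiments cannot
probe.

## Numerical choices and degenerate inputs

- Share normalization tolerance $10^{-12}$; DTM distribution
  normalization asserted at $10^{-8}$.
- Ties in rankings (top-k diseases, top words) break lexicographically so
  exports are deterministic.
- All-zero measure-years, empty vocabularies, empty CUI sets, dangling
  PheCodes and infeasible fold patterns are explicit errors naming the
  offending cell; malformed corpus records are skipped and counted, never
  fatal; zero-denominator years yield no coverage entries.
- Zero-share ROI cells are sentinels, not `Inf`/`NaN`.
- `K` exceeding document or vocabulary count is an error; perfect
  collinearity reports `Inf` VIF with a warning.

## Known limitations

- The recognizer does no word-sense disambiguation, negation handling or
  abbreviation expansion; a mention is a mention.
- Section weighting (title vs claims) is uniform; no position or frequency
  weighting within a document.
- The DTM's EM finds local optima; multi-seed restarts
  (`seeds_per_k`) mitigate but do not eliminate this, and very small
  corpora can make coherence-based selection unstable.
- PHI compares distributions only through total variation; it is
  insensitive to *which* diseases carry the misalignment.
- Measure tables are taken as given; no deflation or demographic
  adjustment of costs is attempted.
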