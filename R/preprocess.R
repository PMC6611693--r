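#' Default stop word list and lemmatization rules
#'
#' The package ships a small English stop word list (function words plus a
#' few patent boilerplate terms like "comprising") and an ordered
#' suffix-rule table for deterministic, rule-based lemmatization
#' ("walking"/"walked"/"walks" all reduce to "walk"). Both are plain-text
#' files under `inst/extdata/` and can be swapped for domain-specific
#' resources via [read_stopwords()] / [read_lemma_rules()].
#'
#' @return `default_stopwords()`: character vector. `default_lemma_rules()`:
#'   tibble with columns `suffix`, `replacement` (ordered; first matching
#'   rule wins).
#' @export
default_stopwords <- function() {
  read_stopwords(system.file("extdata", "stopwords.txt",
                             package = "patentscape", mustWork = TRUE))
}

#' @rdname default_stopwords
#' @export
default_lemma_rules <- function() {
  read_lemma_rules(system.file("extdata", "lemma_rules.tsv",
                               package = "patentscape", mustWork = TRUE))
}

#' @rdname default_stopwords
#' @param path File path: stop words one term per line (`#` comments);
#'   lemma rules tab-separated `suffix`/`replacement` in application order.
#' @export
read_stopwords <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' @rdname default_stopwords
#' @export
read_lemma_rules <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  tab$replacement[is.na(tab$replacement)] <- ""
  tibble::as_tibble(tab[, c("suffix", "replacement")])
}

# CUI tokens stay atomic through the whole pipeline: never lowercased,
# never stopword-filtered, never lemmatized.
.is_cui_token <- function(tokens) grepl("^C[0-9]+$", tokens)

#' Rule-based lemmatization
#'
#' Applies the first matching suffix rule to each token (rules are tried in
#' table order). A rule only fires when the remaining stem keeps at least
#' three characters, so short tokens pass through unchanged. CUI tokens are
#' never touched.
#'
#' @param tokens Character vector.
#' @param rules Tibble from [default_lemma_rules()] / [read_lemma_rules()].
#' @return Character vector of lemmas, same length.
#' @export
lemmatize <- function(tokens, rules = default_lemma_rules()) {
  out <- tokens
  todo <- !.is_cui_token(tokens)
  for (i in seq_len(nrow(rules))) {
    sfx <- rules$suffix[[i]]
    rep <- rules$replacement[[i]]
    hit <- todo & endsWith(out, sfx) &
      (nchar(out) - nchar(sfx) + nchar(rep)) >= 3
    if (any(hit)) {
      out[hit] <- paste0(substr(out[hit], 1, nchar(out[hit]) - nchar(sfx)), rep)
      todo[hit] <- FALSE
    }
  }
  out
}

#' Preprocess a corpus for topic modeling
#'
#' Fixed order of operations per document (title, abstract and claims
#' concatenated in that order):
#' 1. concept recognition with [recognize()] and replacement of each
#'    multiword mention by its CUI token (preserving compound concepts like
#'    "type 2 diabetes" as single vocabulary items);
#' 2. tokenization on non-alphanumeric boundaries;
#' 3. lowercasing (CUI tokens exempt);
#' 4. stop word removal;
#' 5. rule-based lemmatization.
#' Deterministic; documents whose token list ends up empty are kept here
#' (with zero tokens) and dropped, with a message, by [build_matrix()].
#'
#' @param corpus A `patent_corpus` tibble.
#' @param lex Optional [lexicon()]; `NULL` skips concept encoding.
#' @param stopwords Character vector; default packaged list.
#' @param lemma_rules Rule table; default packaged rules.
#' @return Tibble with columns `doc_id`, `year`, `tokens` (list of
#'   character vectors).
#' @export
preprocess_corpus <- function(corpus, lex = NULL,
                              stopwords = default_stopwords(),
                              lemma_rules = default_lemma_rules()) {
  stopwords <- tolower(stopwords)
  toks_out <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    doc <- corpus[i, ]
    mentions <- if (is.null(lex)) NULL else recognize(doc, lex)
    doc_tokens <- character(0)
    for (section in c("title", "abstract", "claims")) {
      toks <- tokenize(doc[[section]][[1]])
      if (length(toks) == 0) next
      if (!is.null(mentions) && nrow(mentions) > 0) {
        m <- mentions[mentions$section == section, , drop = FALSE]
        if (nrow(m) > 0) {
          # replace each mention span (0-based half-open) by its CUI token;
          # spans never overlap, process right-to-left to keep indices valid
          m <- m[order(-m$start), , drop = FALSE]
          for (j in seq_len(nrow(m))) {
            lo <- m$start[[j]] + 1L
            hi <- m$end[[j]]
            toks <- append(toks[-(lo:hi)], m$cui[[j]], after = lo - 1L)
          }
        }
      }
      doc_tokens <- c(doc_tokens, toks)
    }
    cui <- .is_cui_token(doc_tokens)
    doc_tokens[!cui] <- tolower(doc_tokens[!cui])
    keep <- cui | !(doc_tokens %in% stopwords)
    doc_tokens <- doc_tokens[keep]
    toks_out[[i]] <- lemmatize(doc_tokens, lemma_rules)
  }
  tibble::tibble(doc_id = corpus$doc_id,
                 year = as.integer(format(corpus$grant_date, "%Y")),
                 tokens = toks_out)
}

#' Build a time-sliced document-term matrix
#'
#' Bag-of-words counts over the preprocessed corpus, with document-frequency
#' vocabulary filtering and one time slice per calendar year present in the
#' corpus. Documents left empty after vocabulary filtering are dropped with
#' a message.
#'
#' @param tokenized Tibble from [preprocess_corpus()].
#' @param min_df Minimum number of documents a term must occur in.
#' @param max_df_frac Maximum fraction of documents a term may occur in.
#' @return List of class `doc_term_matrix`: `counts` (sparse dgCMatrix,
#'   documents x terms), `vocab` (character), `doc_ids`, `years` (per
#'   document), `slice_index` (per document, 1-based), `slice_years`
#'   (ordered calendar years).
#' @export
build_matrix <- function(tokenized, min_df = 1L, max_df_frac = 1.0) {
  nonempty <- vapply(tokenized$tokens, length, integer(1)) > 0
  tokenized <- tokenized[nonempty, , drop = FALSE]
  if (nrow(tokenized) < 2) stop("need at least 2 non-empty documents")

  df_tab <- table(unlist(lapply(tokenized$tokens, unique)))
  n_docs <- nrow(tokenized)
  vocab <- sort(names(df_tab)[df_tab >= min_df &
                              df_tab <= max_df_frac * n_docs])
  if (length(vocab) == 0) {
    stop("empty vocabulary after document-frequency filtering")
  }

  triplets <- lapply(seq_len(nrow(tokenized)), function(i) {
    tk <- tokenized$tokens[[i]]
    tk <- tk[tk %in% vocab]
    if (length(tk) == 0) return(NULL)
    tab <- table(tk)
    cbind(i = i, j = match(names(tab), vocab), x = as.integer(tab))
  })
  kept <- !vapply(triplets, is.null, logical(1))
  if (sum(kept) < nrow(tokenized)) {
    message(nrow(tokenized) - sum(kept),
            " document(s) empty after vocabulary filtering; dropped")
  }
  tokenized <- tokenized[kept, , drop = FALSE]
  trip <- do.call(rbind, triplets[kept])
  trip[, "i"] <- match(trip[, "i"], which(kept))
  counts <- Matrix::sparseMatrix(i = trip[, "i"], j = trip[, "j"],
                                 x = trip[, "x"],
                                 dims = c(nrow(tokenized), length(vocab)),
                                 dimnames = list(tokenized$doc_id, vocab))
  slice_years <- sort(unique(tokenized$year))
  structure(
    list(counts = counts, vocab = vocab, doc_ids = tokenized$doc_id,
         years = tokenized$year,
         slice_index = match(tokenized$year, slice_years),
         slice_years = slice_years),
    class = "doc_term_matrix"
  )
}

#' Export a document-term matrix
#'
#' Writes the sparse counts as MatrixMarket (`matrix.mtx`), the vocabulary
#' (`terms.txt`, one per line) and document metadata (`docs.csv`: doc_id,
#' year, slice) into a directory.
#'
#' @param dtm A `doc_term_matrix`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_matrix <- function(dtm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dtm$counts, file.path(dir, "matrix.mtx"))
  writeLines(dtm$vocab, file.path(dir, "terms.txt"))
  utils::write.csv(
    data.frame(doc_id = dtm$doc_ids, year = dtm$years,
               slice = dtm$slice_index),
    file.path(dir, "docs.csv"), row.names = FALSE)
  invisible(dir)
}
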