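#' UMass topic coherence
#'
#' Intrinsic coherence from document co-occurrence in the modeled corpus.
#' For a topic's top `top_n` terms \eqn{w_1, ..., w_N} (ordered by
#' probability), the per-slice score is
#' \deqn{\sum_{i<j} \log \frac{D(w_i, w_j) + 1}{D(w_j)}}
#' with \eqn{D(\cdot)} document (co-)occurrence counts from the
#' document-term matrix. A top term absent from the matrix contributes
#' \eqn{D = 0} joint counts (the +1 smooths the numerator); a zero
#' denominator is guarded to 1. Per-topic scores average the slices with
#' equal weight; the mean over topics summarizes the model.
#'
#' @param fit A `dtm_fit`.
#' @param dtm The `doc_term_matrix` the fit shares a vocabulary with.
#' @param top_n Number of top terms per topic and slice.
#' @return List with `per_topic` (numeric vector, one score per topic) and
#'   `mean` (scalar).
#' @export
umass_coherence <- function(fit, dtm, top_n = 10) {
  B <- dtm$counts > 0        # document incidence, sparse logical
  df <- Matrix::colSums(B)
  vocab <- dtm$vocab
  K <- fit$params$K
  Tn <- length(fit$beta)
  per_topic <- numeric(K)
  for (k in seq_len(K)) {
    slice_scores <- numeric(Tn)
    for (t in seq_len(Tn)) {
      terms <- top_words(fit, t, k, top_n)
      idx <- match(terms, vocab)
      present <- !is.na(idx)
      co <- matrix(0, length(terms), length(terms))
      if (any(present)) {
        sub <- B[, idx[present], drop = FALSE]
        co[present, present] <- as.matrix(Matrix::crossprod(sub))
      }
      dfj <- ifelse(present, df[idx], 0)
      s <- 0
      n <- length(terms)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          s <- s + log((co[i, j] + 1) / max(dfj[j], 1))
        }
      }
      slice_scores[t] <- s
    }
    per_topic[k] <- mean(slice_scores)
  }
  list(per_topic = per_topic, mean = mean(per_topic))
}

#' Choose the number of topics by coherence
#'
#' Fits the model at each candidate K (optionally several seeds per K,
#' averaging the mean UMass coherence) and returns the K with the highest
#' average coherence; ties go to the smaller K. A K whose fits all fail is
#' skipped with a warning.
#'
#' @param dtm A `doc_term_matrix`.
#' @param grid Candidate topic numbers. Default `c(2,4,...,20)`.
#' @param params Template [dtm_params()] (its K is overridden; its seed is
#'   the base seed).
#' @param seeds_per_k Number of random restarts averaged per K.
#' @param top_n Top-term list size passed to [umass_coherence()].
#' @return List with `best_k` and `curve` (tibble: `k`, `coherence`, one
#'   row per successful K, ordered by `k`).
#' @export
select_topic_number <- function(dtm, grid = seq(2L, 20L, by = 2L),
                                params = dtm_params(), seeds_per_k = 1L,
                                top_n = 10) {
  stopifnot(length(grid) > 0)
  grid <- sort(unique(as.integer(grid)))
  rows <- list()
  for (k in grid) {
    scores <- numeric(0)
    for (s in seq_len(seeds_per_k)) {
      pk <- params
      pk$K <- k
      pk$seed <- params$seed + (s - 1L)
      fit <- tryCatch(fit_dtm(dtm, pk), error = function(e) e)
      if (inherits(fit, "error")) next
      scores <- c(scores, umass_coherence(fit, dtm, top_n)$mean)
    }
    if (length(scores) == 0) {
      warning("all fits failed for K = ", k, "; skipping")
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(k = k,
                                                coherence = mean(scores))
  }
  if (length(rows) == 0) stop("no candidate K could be fitted")
  curve <- dplyr::bind_rows(rows)
  # max coherence; ties broken by smaller K (curve is ordered by k)
  best <- curve$k[which.max(curve$coherence)]
  list(best_k = best, curve = curve)
}
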