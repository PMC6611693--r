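#' Tabulate disease-by-year document counts
#'
#' Counts, per root PheCode and calendar year, the number of distinct
#' documents mentioning that PheCode (document-level counting: a document
#' mentioning a disease ten times counts once), plus two per-year
#' denominators: the number of documents mentioning at least one disease
#' (`denominators`) and the total number of documents (`n_docs`).
#'
#' @param annotations Tibble from [annotate_corpus()] (`doc_id`, `roots`).
#' @param doc_years Named integer vector mapping `doc_id` to calendar year,
#'   or a tibble with columns `doc_id`, `year`.
#' @return List of class `disease_year_matrix`: `counts` (integer matrix,
#'   rows = PheCodes, columns = years), `denominators` and `n_docs` (named
#'   integer vectors by year).
#' @export
tabulate_disease_year <- function(annotations, doc_years) {
  if (is.data.frame(doc_years)) {
    doc_years <- stats::setNames(as.integer(doc_years$year), doc_years$doc_id)
  }
  missing <- setdiff(annotations$doc_id, names(doc_years))
  if (length(missing) > 0) {
    stop("doc_id(s) without a year: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  years <- as.integer(doc_years[annotations$doc_id])
  all_years <- sort(unique(years))
  diseases <- sort(unique(unlist(annotations$roots)))
  counts <- matrix(0L, nrow = length(diseases), ncol = length(all_years),
                   dimnames = list(diseases, as.character(all_years)))
  has_mention <- vapply(annotations$roots, length, integer(1)) > 0
  for (i in which(has_mention)) {
    yi <- as.character(years[[i]])
    for (d in annotations$roots[[i]]) counts[d, yi] <- counts[d, yi] + 1L
  }
  denom <- vapply(split(has_mention, years), sum, integer(1))
  ndoc <- vapply(split(has_mention, years), length, integer(1))
  structure(
    list(counts = counts,
         denominators = denom[as.character(all_years)],
         n_docs = ndoc[as.character(all_years)]),
    class = "disease_year_matrix"
  )
}

#' Per-year disease coverage
#'
#' Coverage of disease d in year t is the number of documents mentioning d
#' divided by the per-year denominator. The default denominator is the
#' number of documents mentioning at least one disease (so coverage behaves
#' as a share and single-disease coverage never exceeds 1); the
#' `"all_documents"` alternative divides by all documents in the year.
#' Years with a zero denominator yield no columns.
#'
#' @param matrix A `disease_year_matrix` from [tabulate_disease_year()].
#' @param denominator `"any_disease"` (default) or `"all_documents"`.
#' @return A numeric matrix of class `coverage_table` (rows = PheCodes,
#'   columns = years, values in \[0, 1\]).
#' @export
coverage <- function(matrix, denominator = c("any_disease", "all_documents")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "any_disease") matrix$denominators else matrix$n_docs
  keep <- den > 0
  cov <- sweep(matrix$counts[, keep, drop = FALSE], 2, den[keep], `/`)
  class(cov) <- c("coverage_table", class(cov))
  cov
}

#' Number of diseases covered per year
#'
#' Counts, for each year, the PheCodes mentioned by at least one document.
#'
#' @param matrix A `disease_year_matrix`.
#' @return Named integer vector (names = years).
#' @export
diseases_covered_per_year <- function(matrix) {
  apply(matrix$counts > 0, 2, sum)
}

#' Top-k diseases by coverage
#'
#' Ranks diseases by mean coverage over years (default) or by final-year
#' coverage, descending; ties are broken lexicographically by PheCode so the
#' ranking is deterministic.
#'
#' @param cov A `coverage_table` from [coverage()].
#' @param k Positive integer; when k exceeds the number of diseases all are
#'   returned with a warning.
#' @param ranking `"mean-over-years"` or `"final-year"`.
#' @return Tibble with columns `rank`, `phecode`, `statistic`.
#' @export
top_k_diseases <- function(cov, k, ranking = c("mean-over-years", "final-year")) {
  ranking <- match.arg(ranking)
  stopifnot(k >= 1)
  stat <- if (ranking == "mean-over-years") {
    rowMeans(cov)
  } else {
    cov[, ncol(cov)]
  }
  ord <- order(-stat, rownames(cov))
  if (k > nrow(cov)) {
    warning("k = ", k, " exceeds the number of diseases (", nrow(cov),
            "); returning all")
    k <- nrow(cov)
  }
  sel <- ord[seq_len(k)]
  tibble::tibble(rank = seq_len(k), phecode = rownames(cov)[sel],
                 statistic = unname(stat[sel]))
}

#' Export coverage tables as CSV
#'
#' Writes `coverage.csv` (rows = PheCode, columns = years),
#' `diseases_per_year.csv` (year, count) and `top_k.csv` (rank, phecode,
#' statistic) into a directory.
#'
#' @param matrix A `disease_year_matrix`.
#' @param dir Output directory (created if absent).
#' @param k Top-k size for the ranking export.
#' @return `dir`, invisibly.
#' @export
write_coverage_tables <- function(matrix, dir, k = 24) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cov <- coverage(matrix)
  utils::write.csv(
    data.frame(phecode = rownames(cov), as.data.frame(unclass(cov),
               check.names = FALSE), check.names = FALSE),
    file.path(dir, "coverage.csv"), row.names = FALSE)
  dpy <- diseases_covered_per_year(matrix)
  utils::write.csv(data.frame(year = as.integer(names(dpy)), count = dpy),
                   file.path(dir, "diseases_per_year.csv"), row.names = FALSE)
  utils::write.csv(
    suppressWarnings(top_k_diseases(cov, k)),
    file.path(dir, "top_k.csv"), row.names = FALSE)
  invisible(dir)
}
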