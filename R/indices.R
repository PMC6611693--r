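#' Disease-level measure tables
#'
#' The index layer works on a long table of raw yearly measures
#' \eqn{Y_{nd}(t)}: one row per measure, root PheCode and year. The four
#' measures are `b` (burden: treatment cost per million people), `r`
#' (publication count), `c` (clinical-trial count) and `p` (patent-document
#' count). Values are nonnegative; burden is the needs side, the other
#' three approximate the resources invested.
#'
#' @param measure Character vector in `c("b","r","c","p")`.
#' @param phecode Character vector of root PheCodes.
#' @param year Integer vector of calendar years.
#' @param value Nonnegative numeric vector.
#' @return Tibble of class `measure_table`.
#' @export
measure_table <- function(measure, phecode, year, value) {
  measure <- as.character(measure)
  bad <- setdiff(unique(measure), c("b", "r", "c", "p"))
  if (length(bad) > 0) stop("unknown measure code(s): ",
                            paste(bad, collapse = ", "))
  if (any(value < 0)) stop("measure values must be nonnegative")
  out <- tibble::tibble(measure = measure, phecode = as.character(phecode),
                        year = as.integer(year), value = as.numeric(value))
  if (anyDuplicated(out[, c("measure", "phecode", "year")])) {
    stop("duplicate (measure, phecode, year) rows")
  }
  class(out) <- c("measure_table", class(out))
  out
}

#' Read / write measure tables
#'
#' CSV with columns `measure`, `phecode`, `year`, `value`.
#'
#' @param path File path.
#' @return A `measure_table` tibble.
#' @export
read_measures <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(measure = "character",
                                        phecode = "character"))
  measure_table(tab$measure, tab$phecode, tab$year, tab$value)
}

#' @rdname read_measures
#' @param measures A `measure_table`.
#' @export
write_measures <- function(measures, path) {
  utils::write.csv(measures, path, row.names = FALSE)
  invisible(path)
}

#' Normalize measures to within-year shares
#'
#' Raw measures are subject to inflation (costs and publication counts grow
#' over time) and live on incommensurable units, so each measure is turned
#' into a within-measure, within-year share:
#' \deqn{X_{nd}(t) = Y_{nd}(t) / \sum_{d'} Y_{nd'}(t).}
#' Shares sum to one over diseases for every measure-year and are invariant
#' to rescaling a measure-year by any positive constant.
#'
#' @param measures A `measure_table`.
#' @return A `measure_table`-shaped tibble of shares (`normalized_table`).
#' @export
normalize_measures <- function(measures) {
  out <- measures |>
    dplyr::group_by(.data$measure, .data$year) |>
    dplyr::mutate(total = sum(.data$value)) |>
    dplyr::ungroup()
  zero <- dplyr::distinct(out[out$total <= 0, c("measure", "year")])
  if (nrow(zero) > 0) {
    stop("all-zero measure-year(s): ",
         paste(sprintf("(%s, %d)", zero$measure, zero$year), collapse = ", "))
  }
  out <- dplyr::mutate(out, value = .data$value / .data$total)
  out$total <- NULL
  class(out) <- c("normalized_table", "measure_table", class(tibble::tibble()))
  out
}

#' Composite resource share
#'
#' Weighted combination of the three resource shares (publications,
#' clinical trials, patents): \eqn{R_d(t) = \sum_{n \in \{r,c,p\}} w_n
#' X_{nd}(t)}. With weights summing to one, \eqn{\sum_d R_d(t) = 1}.
#'
#' @param X A `normalized_table` from [normalize_measures()].
#' @param weights Named nonnegative numeric vector over `r`, `c`, `p`,
#'   summing to 1. Default: equal thirds.
#' @return Tibble with columns `phecode`, `year`, `R`.
#' @export
resource_composite <- function(X, weights = c(r = 1/3, c = 1/3, p = 1/3)) {
  weights <- .check_weights(weights)
  X |>
    dplyr::filter(.data$measure %in% c("r", "c", "p")) |>
    dplyr::mutate(w = unname(weights[.data$measure])) |>
    dplyr::group_by(.data$phecode, .data$year) |>
    dplyr::summarise(R = sum(.data$w * .data$value), .groups = "drop")
}

.check_weights <- function(weights) {
  stopifnot(all(c("r", "c", "p") %in% names(weights)))
  weights <- weights[c("r", "c", "p")]
  if (any(weights < 0)) stop("resource weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) stop("resource weights must sum to 1")
  weights
}

# Internal: aligned burden share and composite resource share per
# (phecode, year), with absent shares treated as 0.
.burden_vs_resources <- function(X, weights) {
  burden <- X |>
    dplyr::filter(.data$measure == "b") |>
    dplyr::select(phecode = "phecode", year = "year", X_b = "value")
  comp <- resource_composite(X, weights)
  dplyr::full_join(burden, comp, by = c("phecode", "year")) |>
    dplyr::mutate(X_b = dplyr::coalesce(.data$X_b, 0),
                  R = dplyr::coalesce(.data$R, 0))
}

#' Research Opportunity Index
#'
#' Signed fold-imbalance between a disease's share of burden and its share
#' of research resources. With \eqn{\rho_d(t) = X_{bd}(t) / R_d(t)}:
#' ROI \eqn{= \rho} when \eqn{\rho \ge 1} (understudied, positive) and
#' \eqn{= -1/\rho} when \eqn{\rho < 1} (overstudied, negative), so
#' \eqn{|ROI| \ge 1} always and ROI \eqn{= +1} at exact alignment. Zero
#' shares yield explicit sentinels instead of infinities:
#' `"overstudied-unbounded"` (no burden, some resources),
#' `"understudied-unbounded"` (burden, no resources), `"undefined"` (both
#' zero); the `roi` column is `NA` on sentinel rows.
#'
#' @param X A `normalized_table`.
#' @param weights Resource weights as in [resource_composite()].
#' @return Tibble with columns `phecode`, `year`, `roi`, `X_b`, `R`,
#'   `sentinel` (`NA` for finite entries).
#' @export
roi <- function(X, weights = c(r = 1/3, c = 1/3, p = 1/3)) {
  tab <- .burden_vs_resources(X, weights)
  rho <- tab$X_b / tab$R
  value <- ifelse(rho >= 1, rho, -1 / rho)
  sentinel <- rep(NA_character_, nrow(tab))
  sentinel[tab$X_b == 0 & tab$R > 0] <- "overstudied-unbounded"
  sentinel[tab$X_b > 0 & tab$R == 0] <- "understudied-unbounded"
  sentinel[tab$X_b == 0 & tab$R == 0] <- "undefined"
  value[!is.na(sentinel)] <- NA_real_
  dplyr::arrange(
    tibble::tibble(phecode = tab$phecode, year = tab$year, roi = value,
                   X_b = tab$X_b, R = tab$R, sentinel = sentinel),
    .data$phecode, .data$year)
}

#' Public Health Index
#'
#' Per-year scalar misalignment between the burden share distribution and
#' the composite resource share distribution over all diseases: the total
#' variation distance \deqn{PHI(t) = \tfrac12 \sum_d |X_{bd}(t) - R_d(t)|.}
#' PHI lies in \[0, 1\]; 0 means burden and resource shares coincide for
#' every disease (perfect alignment), and smaller values mean better
#' overall alignment.
#'
#' @param X A `normalized_table`.
#' @param weights Resource weights as in [resource_composite()].
#' @return Tibble with columns `year`, `phi`.
#' @export
phi <- function(X, weights = c(r = 1/3, c = 1/3, p = 1/3)) {
  .burden_vs_resources(X, weights) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(phi = 0.5 * sum(abs(.data$X_b - .data$R)),
                     .groups = "drop") |>
    dplyr::arrange(.data$year)
}

#' Variance inflation factors across the four measures
#'
#' Multicollinearity audit: for each measure, its cross-disease share
#' vector is regressed (least squares, with intercept) on the other three,
#' and \eqn{VIF = 1/(1 - R^2)} is reported. Observations are
#' (phecode, year) cells, pooled over years by default or restricted to a
#' single year.
#'
#' @param X A `normalized_table` containing all four measures.
#' @param year Optional single year; default pools all years.
#' @return Tibble with columns `measure`, `r_squared`, `vif`. Perfect
#'   collinearity is reported as `Inf` with a warning.
#' @export
vif_audit <- function(X, year = NULL) {
  if (!is.null(year)) X <- X[X$year == year, , drop = FALSE]
  wide <- tidyr::pivot_wider(X[, c("measure", "phecode", "year", "value")],
                             names_from = "measure", values_from = "value")
  wide <- wide[stats::complete.cases(wide[, c("b", "r", "c", "p")]), ]
  if (nrow(wide) < 5) {
    stop("vif_audit needs at least 5 complete (phecode, year) rows")
  }
  out <- lapply(c("b", "r", "c", "p"), function(m) {
    others <- setdiff(c("b", "r", "c", "p"), m)
    fml <- stats::reformulate(others, response = m)
    r2 <- summary(stats::lm(fml, data = wide))$r.squared
    v <- if (r2 >= 1 - 1e-12) {
      warning("perfect collinearity: measure ", m, " has R^2 = 1")
      Inf
    } else 1 / (1 - r2)
    tibble::tibble(measure = m, r_squared = r2, vif = v)
  })
  dplyr::bind_rows(out)
}

#' Export index tables as CSV
#'
#' Writes `roi.csv`, `phi.csv` and `vif.csv` into a directory.
#'
#' @param X A `normalized_table`.
#' @param dir Output directory.
#' @param weights Resource weights.
#' @return `dir`, invisibly.
#' @export
write_index_tables <- function(X, dir, weights = c(r = 1/3, c = 1/3, p = 1/3)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(roi(X, weights), file.path(dir, "roi.csv"),
                   row.names = FALSE)
  utils::write.csv(phi(X, weights), file.path(dir, "phi.csv"),
                   row.names = FALSE)
  utils::write.csv(vif_audit(X), file.path(dir, "vif.csv"), row.names = FALSE)
  invisible(dir)
}
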