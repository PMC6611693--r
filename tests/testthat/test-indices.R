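mk_measures <- function(values, measures = c("b", "r", "c", "p"),
                        year = 2000L) {
  # values: named list measure -> numeric vector over diseases
  rows <- lapply(measures, function(m) {
    v <- values[[m]]
    tibble::tibble(measure = m, phecode = sprintf("%03d", seq_along(v)),
                   year = year, value = v)
  })
  tab <- dplyr::bind_rows(rows)
  measure_table(tab$measure, tab$phecode, tab$year, tab$value)
}

test_that("normalization produces within-measure-year shares", {
  Y <- mk_measures(list(b = c(2, 3, 5), r = c(1, 1, 1),
                        c = c(10, 0, 0), p = c(4, 4, 2)))
  X <- normalize_measures(Y)
  xb <- X$value[X$measure == "b"]
  expect_equal(xb, c(0.2, 0.3, 0.5))
  sums <- X |> dplyr::group_by(measure, year) |>
    dplyr::summarise(s = sum(value), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # single disease: share forced to 1
  one <- measure_table("b", "001", 2000L, 7)
  expect_equal(normalize_measures(one)$value, 1)
  # scale invariance per measure-year
  Y2 <- Y
  Y2$value[Y2$measure == "b"] <- Y2$value[Y2$measure == "b"] * 1000
  expect_equal(normalize_measures(Y2)$value, X$value)
})

test_that("an all-zero measure-year is an explicit error naming the cell", {
  Y <- mk_measures(list(b = c(0, 0), r = c(1, 2), c = c(1, 1), p = c(1, 1)))
  expect_error(normalize_measures(Y), "\\(b, 2000\\)")
})

test_that("resource composite is the weighted share mixture", {
  X <- normalize_measures(mk_measures(list(
    b = c(1, 1), r = c(0.1, 0.9), c = c(0.2, 0.8), p = c(0.4, 0.6))))
  R <- resource_composite(X)
  expect_equal(R$R[R$phecode == "001"], (0.1 + 0.2 + 0.4) / 3)
  R1 <- resource_composite(X, weights = c(r = 1, c = 0, p = 0))
  expect_equal(R1$R[R1$phecode == "001"], 0.1)
  expect_equal(sum(R$R), 1)
  expect_error(resource_composite(X, weights = c(r = -1, c = 1, p = 1)),
               "nonnegative")
  expect_error(resource_composite(X, weights = c(r = 1, c = 1, p = 1)),
               "sum to 1")
})

test_that("roi follows the signed-fold form with sentinels at zero shares", {
  # shares constructed directly: burden (0.1, 0.3, 0.3, 0, 0.3),
  # all three resources (0.2, 0.1, 0.3, 0.2, 0.2)
  X <- normalize_measures(mk_measures(list(
    b = c(0.1, 0.3, 0.3, 0, 0.3),
    r = c(0.2, 0.1, 0.3, 0.2, 0.2),
    c = c(0.2, 0.1, 0.3, 0.2, 0.2),
    p = c(0.2, 0.1, 0.3, 0.2, 0.2))))
  out <- roi(X)
  expect_equal(out$roi, c(-2, 3, 1, NA, 1.5))
  expect_identical(out$sentinel[[4]], "overstudied-unbounded")
  # sign test: roi > 0 iff burden share exceeds composite resource share
  fin <- !is.na(out$roi)
  expect_identical(out$roi[fin] > 0 | out$roi[fin] == 1,
                   out$X_b[fin] >= out$R[fin])
})

test_that("swapping burden and resources flips every finite roi sign", {
  X <- normalize_measures(mk_measures(list(
    b = c(0.1, 0.3, 0.6), r = c(0.3, 0.2, 0.5),
    c = c(0.3, 0.2, 0.5), p = c(0.3, 0.2, 0.5))))
  swapped <- normalize_measures(mk_measures(list(
    b = c(0.3, 0.2, 0.5), r = c(0.1, 0.3, 0.6),
    c = c(0.1, 0.3, 0.6), p = c(0.1, 0.3, 0.6))))
  a <- roi(X)$roi
  b <- roi(swapped)$roi
  expect_equal(b[abs(a) > 1], -a[abs(a) > 1])
  expect_equal(b[a == 1], a[a == 1])  # alignment stays +1
})

test_that("phi is the total-variation distance between share distributions", {
  aligned <- normalize_measures(mk_measures(list(
    b = c(0.4, 0.6), r = c(0.4, 0.6), c = c(0.4, 0.6), p = c(0.4, 0.6))))
  expect_equal(phi(aligned)$phi, 0)
  maximal <- normalize_measures(mk_measures(list(
    b = c(1, 0), r = c(0, 1), c = c(0, 1), p = c(0, 1))))
  expect_equal(phi(maximal)$phi, 1)
  hand <- normalize_measures(mk_measures(list(
    b = c(0.6, 0.4), r = c(0.5, 0.5), c = c(0.5, 0.5), p = c(0.5, 0.5))))
  expect_equal(phi(hand)$phi, 0.1)
})

test_that("moving resources toward the burden distribution never raises phi", {
  set.seed(13)
  for (rep in 1:20) {
    n <- 6
    xb <- as.numeric(rmultinom(1, 1000, rep(1, n))) / 1000
    r0 <- as.numeric(rmultinom(1, 1000, rep(1, n))) / 1000
    lam <- runif(1)
    r1 <- (1 - lam) * r0 + lam * xb  # pointwise contraction toward burden
    phi_of <- function(r) {
      X <- normalize_measures(mk_measures(list(b = xb, r = r, c = r, p = r)))
      phi(X)$phi
    }
    expect_lte(phi_of(r1), phi_of(r0) + 1e-12)
  }
})

test_that("vif matches the closed form and flags degeneracies", {
  set.seed(7)
  n <- 40
  # mutually orthogonal predictors, all orthogonal to the intercept: VIF 1
  M <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n, 4))))[, 2:5]
  ortho <- tibble::tibble(
    measure = rep(c("b", "r", "c", "p"), each = n),
    phecode = rep(sprintf("%03d", 1:n), 4),
    year = 2000L,
    value = c(M[, 1], M[, 2], M[, 3], M[, 4]))
  v <- vif_audit(ortho)
  expect_equal(v$vif, rep(1, 4), tolerance = 1e-10)

  # an exact copy of another measure: infinite VIF with warning
  copycat <- ortho
  copycat$value[copycat$measure == "b"] <-
    copycat$value[copycat$measure == "r"]
  w <- capture_warnings(v2 <- vif_audit(copycat))
  expect_true(any(grepl("collinearity", w)))
  expect_true(is.infinite(v2$vif[v2$measure == "b"]))

  expect_error(vif_audit(ortho[ortho$phecode %in% sprintf("%03d", 1:3), ]),
               "at least 5")
})

test_that("a construction with known R-squared 0.75 gives VIF 4", {
  set.seed(21)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  yhat <- 1 + 0.5 * x1 - 0.3 * x2 + 0.8 * x3
  # residual orthogonal to the predictors and intercept, scaled so that
  # SSE = SSR / 3  =>  R^2 = 0.75 exactly
  e <- residuals(lm(rnorm(n) ~ x1 + x2 + x3))
  ssr <- sum((yhat - mean(yhat))^2)
  e <- e * sqrt(ssr / 3 / sum(e^2))
  y <- yhat + e
  tab <- tibble::tibble(
    measure = rep(c("b", "r", "c", "p"), each = n),
    phecode = rep(sprintf("%03d", 1:n), 4),
    year = 2000L,
    value = c(y, x1, x2, x3))
  v <- vif_audit(tab)
  expect_equal(v$vif[v$measure == "b"], 4, tolerance = 1e-8)

  # brute-force oracle: normal equations by hand
  Xd <- cbind(1, x1, x2, x3)
  bhat <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  r2 <- 1 - sum((y - Xd %*% bhat)^2) / sum((y - mean(y))^2)
  expect_equal(v$vif[v$measure == "b"], 1 / (1 - r2), tolerance = 1e-8)
})
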