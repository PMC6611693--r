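#' Dynamic topic model parameters
#'
#' @param K Number of topics (>= 2 for real use; K = 1 allowed for the
#'   degenerate single-topic limit).
#' @param alpha Document-topic concentration (> 0); smaller values
#'   concentrate each document on fewer topics. Default 0.01.
#' @param sigma Variance of the Gaussian random walk tying each topic's
#'   natural (log-scale) parameters between adjacent time slices (>= 0);
#'   smaller values force more similar word distributions over time, 0 ties
#'   the slices exactly. Default 0.005.
#' @param n_iter Maximum EM epochs.
#' @param seed Random seed; identical inputs and seed give bitwise-identical
#'   fits.
#' @param tol Relative objective-change convergence tolerance.
#' @return List of class `dtm_params`.
#' @export
dtm_params <- function(K = 10L, alpha = 0.01, sigma = 0.005, n_iter = 60L,
                       seed = 1L, tol = 1e-6) {
  stopifnot(K >= 1, alpha > 0, sigma >= 0, n_iter >= 1)
  structure(list(K = as.integer(K), alpha = alpha, sigma = sigma,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 tol = tol),
            class = "dtm_params")
}

# Row-wise softmax with log-sum-exp stabilization.
.softmax_rows <- function(eta) {
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

#' Fit a dynamic topic model
#'
#' Topics are per-slice multinomial word distributions whose natural
#' parameters \eqn{\eta_{tk}} follow a Gaussian random walk between
#' adjacent slices, \eqn{\eta_{tk} \sim N(\eta_{t-1,k}, \sigma I)};
#' \eqn{\beta_{tk} = softmax(\eta_{tk})}. Document topic proportions
#' \eqn{\theta_d} are governed by the concentration `alpha`. Inference is a
#' penalized EM: the E-step computes expected topic-word counts per slice
#' under the current parameters; the M-step takes gradient steps (with
#' backtracking line search) on the chain-penalized likelihood of the
#' natural parameters, and document proportions are updated as
#' \eqn{\theta_{dk} \propto N_{dk} + \alpha}. The recorded objective
#' (penalized log posterior) is nondecreasing over epochs; with
#' `sigma = 0` the slices are tied exactly and the M-step is the closed-form
#' pooled estimate.
#'
#' @param dtm A `doc_term_matrix` from [build_matrix()].
#' @param params A [dtm_params()] object.
#' @return List of class `dtm_fit`: `beta` (list over slices of K x V
#'   matrices, rows sum to 1, strictly positive), `eta` (natural
#'   parameters, same shape), `theta` (D x K, rows sum to 1), `loglik`
#'   (objective trace per epoch), `converged`, plus `vocab`, `slice_years`,
#'   `doc_ids`, `params`.
#' @export
fit_dtm <- function(dtm, params = dtm_params()) {
  stopifnot(inherits(dtm, "doc_term_matrix"), inherits(params, "dtm_params"))
  X <- as.matrix(dtm$counts)
  D <- nrow(X)
  V <- ncol(X)
  K <- params$K
  if (K > V) stop("K = ", K, " exceeds vocabulary size ", V)
  if (K > D) stop("K = ", K, " exceeds document count ", D)
  Tn <- length(dtm$slice_years)
  slice_docs <- split(seq_len(D), dtm$slice_index)
  sigma <- params$sigma
  alpha <- params$alpha
  smooth <- 1e-6

  set.seed(params$seed)
  theta <- matrix(stats::rgamma(D * K, shape = 1), D, K)
  theta <- theta / rowSums(theta)
  base_eta <- log(colSums(X) + smooth * sum(X) / V)
  eta <- lapply(seq_len(Tn), function(t) {
    e <- matrix(rep(base_eta, each = K), K, V) +
      matrix(stats::rnorm(K * V, sd = 0.25), K, V)
    if (t == 1) e else NULL
  })
  # same initial noise in every slice: start the chain flat
  for (t in seq_len(Tn)) eta[[t]] <- eta[[1]]
  beta <- lapply(eta, .softmax_rows)

  chain_penalty <- function(eta) {
    if (sigma == 0 || Tn == 1) return(0)
    s <- 0
    for (t in 2:Tn) s <- s + sum((eta[[t]] - eta[[t - 1]])^2)
    s / (2 * sigma)
  }
  data_loglik <- function(beta, theta) {
    ll <- 0
    for (t in seq_len(Tn)) {
      d <- slice_docs[[t]]
      S <- theta[d, , drop = FALSE] %*% beta[[t]]
      Xt <- X[d, , drop = FALSE]
      nz <- Xt > 0
      ll <- ll + sum(Xt[nz] * log(S[nz]))
    }
    ll
  }
  objective <- function(beta, theta, eta) {
    data_loglik(beta, theta) + alpha * sum(log(theta)) - chain_penalty(eta)
  }

  n_tokens <- sum(X)
  trace <- numeric(0)
  obj <- objective(beta, theta, eta)
  converged <- FALSE

  for (epoch in seq_len(params$n_iter)) {
    # E-step part 1: update document proportions (MAP EM step, monotone
    # in the penalized objective for fixed beta)
    for (t in seq_len(Tn)) {
      d <- slice_docs[[t]]
      Th <- theta[d, , drop = FALSE]
      S <- Th %*% beta[[t]]
      Rt <- X[d, , drop = FALSE] / S
      Nt <- Th * (Rt %*% t(beta[[t]]))            # D_t x K
      theta_new <- Nt + alpha
      theta[d, ] <- theta_new / rowSums(theta_new)
    }
    # E-step part 2: expected topic-word counts at the updated theta, so
    # the M-step carries the usual EM ascent guarantee
    C <- vector("list", Tn)   # K x V expected counts per slice
    for (t in seq_len(Tn)) {
      d <- slice_docs[[t]]
      Th <- theta[d, , drop = FALSE]
      Rt <- X[d, , drop = FALSE] / (Th %*% beta[[t]])
      C[[t]] <- beta[[t]] * (t(Th) %*% Rt)
    }

    # M-step on natural parameters
    if (sigma == 0) {
      Cpool <- Reduce(`+`, C)
      bpool <- (Cpool + smooth) / (rowSums(Cpool) + smooth * V)
      for (t in seq_len(Tn)) {
        beta[[t]] <- bpool
        eta[[t]] <- log(bpool)
      }
    } else {
      Nk <- lapply(C, rowSums)
      step <- 1 / (max(unlist(Nk)) + 2 / sigma)
      cur <- data_loglik(beta, theta) - chain_penalty(eta)
      for (gstep in 1:3) {
        grad <- vector("list", Tn)
        for (t in seq_len(Tn)) {
          g <- C[[t]] - Nk[[t]] * beta[[t]]
          if (t > 1) g <- g - (eta[[t]] - eta[[t - 1]]) / sigma
          if (t < Tn) g <- g - (eta[[t]] - eta[[t + 1]]) / sigma
          grad[[t]] <- g
        }
        s <- step
        improved <- FALSE
        for (bt in 1:12) {
          eta_try <- lapply(seq_len(Tn), function(t) eta[[t]] + s * grad[[t]])
          beta_try <- lapply(eta_try, .softmax_rows)
          val <- data_loglik(beta_try, theta) - chain_penalty(eta_try)
          if (val >= cur) {
            eta <- eta_try
            beta <- beta_try
            cur <- val
            improved <- TRUE
            break
          }
          s <- s / 2
        }
        if (!improved) break
      }
    }

    obj_new <- objective(beta, theta, eta)
    trace <- c(trace, obj_new)
    if (epoch > 1 &&
        abs(obj_new - obj) <= params$tol * max(1, n_tokens)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  if (!converged) {
    # best fit so far is returned; flag, don't fail
  }

  for (t in seq_len(Tn)) {
    dimnames(beta[[t]]) <- list(NULL, dtm$vocab)
  }
  structure(
    list(beta = beta, eta = eta, theta = theta, loglik = trace,
         converged = converged, vocab = dtm$vocab,
         slice_years = dtm$slice_years, doc_ids = dtm$doc_ids,
         params = params),
    class = "dtm_fit"
  )
}

#' @export
print.dtm_fit <- function(x, ...) {
  cat(sprintf("Dynamic topic model fit: K = %d topics, %d slices (%s), %d docs\n",
              x$params$K, length(x$slice_years),
              paste(range(x$slice_years), collapse = "-"),
              nrow(x$theta)))
  cat(sprintf("  alpha = %g, sigma = %g, %sconverged after %d epochs\n",
              x$params$alpha, x$params$sigma,
              if (x$converged) "" else "NOT ", length(x$loglik)))
  invisible(x)
}

#' Top terms of a topic at a slice
#'
#' The `n` highest-probability terms of topic `k` in slice `t`, ties broken
#' lexicographically. `n` larger than the vocabulary returns all terms.
#'
#' @param fit A `dtm_fit`.
#' @param t Slice index (1-based) or calendar year present in
#'   `fit$slice_years`.
#' @param k Topic index.
#' @param n Number of terms.
#' @return Character vector of terms, most probable first.
#' @export
top_words <- function(fit, t, k, n = 10) {
  if (t %in% fit$slice_years && !(t %in% seq_along(fit$slice_years))) {
    t <- match(t, fit$slice_years)
  }
  stopifnot(t >= 1, t <= length(fit$beta), k >= 1, k <= fit$params$K)
  b <- fit$beta[[t]][k, ]
  ord <- order(-b, fit$vocab)
  fit$vocab[ord[seq_len(min(n, length(b)))]]
}

#' Keyword drift table
#'
#' For each topic, collects the union over slices of its top-`n` terms and
#' reports the first and last slice (calendar years) in which each term was
#' in the top `n` - the keyword-evolution view of a fitted model.
#'
#' @param fit A `dtm_fit`.
#' @param n Top-list size per slice.
#' @return Tibble with columns `topic`, `term`, `first_year`, `last_year`,
#'   `n_slices`.
#' @export
top_word_drift <- function(fit, n = 10) {
  rows <- list()
  for (k in seq_len(fit$params$K)) {
    membership <- lapply(seq_along(fit$beta), function(t) top_words(fit, t, k, n))
    terms <- unique(unlist(membership))
    for (term in terms) {
      present <- vapply(membership, function(tw) term %in% tw, logical(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        topic = k, term = term,
        first_year = fit$slice_years[which(present)[1]],
        last_year = fit$slice_years[utils::tail(which(present), 1)],
        n_slices = sum(present))
    }
  }
  dplyr::bind_rows(rows)
}

#' Export top words per slice and topic as CSV
#'
#' @param fit A `dtm_fit`.
#' @param path Output CSV (columns slice_year, topic, rank, term, beta).
#' @param n Terms per topic and slice.
#' @return `path`, invisibly.
#' @export
write_top_words <- function(fit, path, n = 10) {
  rows <- list()
  for (t in seq_along(fit$beta)) {
    for (k in seq_len(fit$params$K)) {
      tw <- top_words(fit, t, k, n)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        slice_year = fit$slice_years[[t]], topic = k,
        rank = seq_along(tw), term = tw,
        beta = fit$beta[[t]][k, tw])
    }
  }
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}

#' Match fitted topics to reference topics by cosine similarity
#'
#' Greedy assignment: repeatedly pairs the most cosine-similar
#' (reference, fitted) topic pair among those still unassigned. Used by
#' recovery tests to compare a fit against planted topic distributions.
#'
#' @param beta_ref Reference K x V matrix (rows = topics).
#' @param beta_fit Fitted K' x V matrix on the same vocabulary.
#' @return Tibble with columns `ref`, `fit`, `cosine`.
#' @export
topic_match <- function(beta_ref, beta_fit) {
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim <- outer(seq_len(nrow(beta_ref)), seq_len(nrow(beta_fit)),
               Vectorize(function(i, j) cos(beta_ref[i, ], beta_fit[j, ])))
  out <- list()
  while (length(out) < min(nrow(beta_ref), nrow(beta_fit))) {
    best <- which(sim == max(sim, na.rm = TRUE), arr.ind = TRUE)[1, ]
    out[[length(out) + 1L]] <- tibble::tibble(
      ref = best[[1]], fit = best[[2]], cosine = sim[best[[1]], best[[2]]])
    sim[best[[1]], ] <- NA
    sim[, best[[2]]] <- NA
  }
  dplyr::bind_rows(out)
}
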