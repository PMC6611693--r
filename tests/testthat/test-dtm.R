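# Corpus of filler tokens drawn from planted per-slice topic distributions.
topic_corpus <- function(seed, K_true = 2, vocab = 20, years = 2000:2002,
                         docs_per_year = 60, tokens = 40, drift = NULL) {
  cfg <- synth_config(seed = seed, years = years,
                      docs_per_year = docs_per_year, mention_prob = 0,
                      biomedical_fraction = 1, tokens_per_doc = tokens,
                      topics = list(K_true = K_true, vocab_size = vocab,
                                    drift = drift))
  sim <- make_corpus(cfg, make_lexicon_and_mappings(cfg))
  list(dtm = build_matrix(preprocess_corpus(sim$corpus)),
       beta = sim$truth$beta)
}

test_that("sigma = 0 with one topic degenerates to the corpus distribution", {
  cc <- topic_corpus(1, K_true = 2)
  fit <- fit_dtm(cc$dtm, dtm_params(K = 1, sigma = 0, n_iter = 10, seed = 1))
  corpus_dist <- Matrix::colSums(cc$dtm$counts) / sum(cc$dtm$counts)
  for (t in seq_along(fit$beta)) {
    expect_equal(fit$beta[[t]][1, ], corpus_dist, tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
  # identical across slices
  expect_identical(fit$beta[[1]], fit$beta[[2]])
})

test_that("fits are bitwise identical for identical inputs and seed", {
  cc <- topic_corpus(2)
  f1 <- fit_dtm(cc$dtm, dtm_params(K = 2, n_iter = 15, seed = 9))
  f2 <- fit_dtm(cc$dtm, dtm_params(K = 2, n_iter = 15, seed = 9))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("all fitted distributions normalize and stay strictly positive", {
  cc <- topic_corpus(3)
  for (sg in c(0, 0.005)) {
    fit <- fit_dtm(cc$dtm, dtm_params(K = 3, sigma = sg, n_iter = 15,
                                      seed = 2))
    for (t in seq_along(fit$beta)) {
      expect_equal(rowSums(fit$beta[[t]]), rep(1, 3), tolerance = 1e-8)
      expect_true(all(fit$beta[[t]] > 0))
    }
    expect_equal(rowSums(fit$theta), rep(1, nrow(fit$theta)),
                 tolerance = 1e-8)
  }
})

test_that("the optimization objective is nondecreasing over epochs", {
  cc <- topic_corpus(4)
  n_tokens <- sum(cc$dtm$counts)
  for (sg in c(0, 0.005)) {
    fit <- fit_dtm(cc$dtm, dtm_params(K = 2, sigma = sg, n_iter = 40,
                                      seed = 3))
    drops <- diff(fit$loglik)
    expect_true(all(drops >= -1e-6 * n_tokens))
  }
})

test_that("degenerate topic counts are rejected", {
  cc <- topic_corpus(5, vocab = 12, docs_per_year = 5, years = 2000)
  expect_error(fit_dtm(cc$dtm, dtm_params(K = 30)), "vocabulary|document")
})

test_that("well-separated planted topics are recovered", {
  cc <- topic_corpus(6)
  fit <- fit_dtm(cc$dtm, dtm_params(K = 2, n_iter = 40, seed = 1))
  bmean <- Reduce(`+`, fit$beta) / length(fit$beta)
  mm <- topic_match(cc$beta[[1]][, fit$vocab], bmean)
  expect_true(all(mm$cosine >= 0.9))
})

test_that("shrinking sigma shrinks between-slice topic movement", {
  cc <- topic_corpus(7, docs_per_year = 15)
  fit_small <- fit_dtm(cc$dtm, dtm_params(K = 2, sigma = 1e-4, n_iter = 30,
                                          seed = 4))
  fit_big <- fit_dtm(cc$dtm, dtm_params(K = 2, sigma = 0.05, n_iter = 30,
                                        seed = 4))
  move <- function(fit) max(abs(fit$beta[[2]] - fit$beta[[1]]))
  expect_lt(move(fit_small), move(fit_big))
  fit_zero <- fit_dtm(cc$dtm, dtm_params(K = 2, sigma = 0, n_iter = 30,
                                         seed = 4))
  expect_equal(move(fit_zero), 0)
  expect_lte(move(fit_small), 10 * max(1e-12, move(fit_zero)) + 1e-3)
})

test_that("top_words ranks by beta with lexicographic tie-break", {
  fit <- structure(list(
    beta = list(matrix(c(0.2, 0.3, 0.2, 0.3), 1,
                       dimnames = list(NULL, c("phenyl", "aryl", "keto",
                                               "ester")))),
    vocab = c("phenyl", "aryl", "keto", "ester"),
    slice_years = 2000L,
    params = dtm_params(K = 1)), class = "dtm_fit")
  expect_identical(top_words(fit, 1, 1, 2), c("aryl", "ester"))
  expect_identical(top_words(fit, 1, 1, 3), c("aryl", "ester", "keto"))
  # n beyond the vocabulary returns everything
  expect_identical(length(top_words(fit, 1, 1, 99)), 4L)
})

test_that("the keyword-drift table matches a brute-force recount", {
  cc <- topic_corpus(8, drift = list(topic = 1, term = 1, start = 0.02,
                                     end = 0.35), years = 2000:2003)
  fit <- fit_dtm(cc$dtm, dtm_params(K = 2, n_iter = 30, seed = 5))
  drift_tab <- top_word_drift(fit, n = 5)
  for (i in sample(nrow(drift_tab), 10)) {
    row <- drift_tab[i, ]
    present <- vapply(seq_along(fit$beta), function(t)
      row$term %in% top_words(fit, t, row$topic, 5), logical(1))
    expect_identical(fit$slice_years[which(present)[1]], row$first_year)
    expect_identical(fit$slice_years[max(which(present))], row$last_year)
    expect_identical(sum(present), row$n_slices)
  }
})
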