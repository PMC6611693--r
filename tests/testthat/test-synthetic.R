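test_that("ambiguity wiring is exact in the generated mapping bundle", {
  cfg0 <- synth_config(seed = 1, n_diseases = 10, ambiguity_fraction = 0)
  a0 <- mapping_audit(make_lexicon_and_mappings(cfg0)$bundle,
                      make_lexicon_and_mappings(cfg0)$truth$cui)
  expect_equal(a0$definitive_pct, 100)

  cfg5 <- synth_config(seed = 1, n_diseases = 10, ambiguity_fraction = 0.5)
  lm5 <- make_lexicon_and_mappings(cfg5)
  a5 <- mapping_audit(lm5$bundle, lm5$truth$cui)
  expect_identical(a5$n_ambiguous, 5L)
  expect_error(synth_config(ambiguity_fraction = 1.5), "ambiguity_fraction")
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- synth_preset_demo(seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("a disease with mention probability 1 reaches every biomedical doc", {
  cfg <- synth_config(seed = 9, docs_per_year = 40,
                      mention_prob = c(1, rep(0.1, 7)))
  lexmap <- make_lexicon_and_mappings(cfg)
  sim <- make_corpus(cfg, lexmap)
  filt <- filter_corpus(sim$corpus, sim$criteria)$corpus
  ann <- annotate_corpus(filt, lexmap$lexicon, lexmap$bundle)
  expect_true(all(vapply(ann$roots, function(r) "001" %in% r, logical(1))))
})

test_that("planted biomedical fraction is recovered by the filter", {
  cfg <- synth_config(seed = 15, years = 2000:2001, docs_per_year = 500,
                      biomedical_fraction = 0.3, tokens_per_doc = 5,
                      topics = list(K_true = 2, vocab_size = 10))
  sim <- make_corpus(cfg, make_lexicon_and_mappings(cfg))
  rep <- filter_corpus(sim$corpus, sim$criteria)$report
  p_hat <- rep$n_biomedical / rep$n_total
  se <- sqrt(0.3 * 0.7 / rep$n_total)
  expect_lt(abs(p_hat - 0.3), 3 * se)
  # the report's biomedical flags coincide with the planted ones
  expect_identical(rep$n_biomedical, sum(sim$truth$docs$biomedical))
})

test_that("planted per-slice topic distributions match token frequencies", {
  cfg <- synth_config(seed = 25, years = 2000, docs_per_year = 300,
                      mention_prob = 0, biomedical_fraction = 1,
                      tokens_per_doc = 50,
                      topics = list(K_true = 2, vocab_size = 10))
  sim <- make_corpus(cfg, make_lexicon_and_mappings(cfg))
  # pool empirical frequencies per planted topic and compare to truth
  tok <- preprocess_corpus(sim$corpus)
  for (k in 1:2) {
    ids <- sim$truth$docs$doc_id[sim$truth$docs$topic == k]
    emp <- table(factor(unlist(tok$tokens[tok$doc_id %in% ids]),
                        levels = sim$truth$vocab))
    emp <- as.numeric(emp) / sum(emp)
    truth <- sim$truth$beta[[1]][k, ]
    n <- sum(sim$truth$docs$topic == k) * cfg$tokens_per_doc
    tol <- 3 * sqrt(pmax(truth * (1 - truth), 1e-12) / n)
    expect_true(all(abs(emp - truth) <= tol + 1e-12))
  }
})

test_that("noiseless planted folds reproduce through the index pipeline", {
  cfg <- synth_config(seed = 2, measure_spec = list(
    folds = c(3, 2, 1, 1, 0.5, 0.5, 1, 1),
    totals = c(b = 1e4, r = 1e4, c = 1e4, p = 1e4), noise = "none"))
  meas <- make_measures(cfg)
  out <- roi(normalize_measures(meas$measures))
  joined <- merge(out, meas$truth, by = c("phecode", "year"))
  expect_equal(joined$roi, joined$expected_roi, tolerance = 1e-12)
  # all folds 1 -> perfect alignment
  cfg1 <- synth_config(seed = 2, measure_spec = list(
    folds = rep(1, 8), totals = c(b = 1e3, r = 1e3, c = 1e3, p = 1e3),
    noise = "none"))
  X1 <- normalize_measures(make_measures(cfg1)$measures)
  expect_equal(roi(X1)$roi, rep(1, 24))
  expect_equal(phi(X1)$phi, rep(0, 3))
})

test_that("infeasible fold patterns are rejected with an explanation", {
  cfg <- synth_config(seed = 2, measure_spec = list(
    folds = rep(2, 8), totals = c(b = 1e3, r = 1e3, c = 1e3, p = 1e3),
    noise = "none"))
  expect_error(make_measures(cfg), "straddle")
})

test_that("written files validate against the package readers with no skips", {
  cfg <- synth_preset_demo(seed = 5)
  dir <- withr::local_tempdir()
  sim <- simulate_study(cfg, dir, dialect = "xml")
  corpus <- read_corpus(sim$paths$corpus, "xml")
  expect_identical(attr(corpus, "n_skipped"), 0L)
  lex <- read_lexicon(sim$paths$lexicon)
  expect_identical(nrow(lex), cfg$n_diseases)
  bundle <- mapping_bundle(read_mapping_table(sim$paths$cui_to_icd9),
                           read_mapping_table(sim$paths$icd9_to_phecode),
                           read_mapping_table(sim$paths$phecode_to_root))
  expect_s3_class(bundle, "mapping_bundle")
  meas <- read_measures(sim$paths$measures)
  expect_s3_class(meas, "measure_table")
})
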