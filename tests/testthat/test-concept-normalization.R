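test_that("recognizer takes the longest match and suppresses nested terms", {
  doc <- patent_corpus("X1", "2001-01-01",
                       title = "Methods of treating type 2 diabetes mellitus")
  m <- recognize(doc, tiny_lexicon())
  expect_identical(nrow(m), 1L)
  expect_identical(m$surface, "type 2 diabetes mellitus")
  expect_identical(m$cui, "C0011860")
  expect_identical(m$end - m$start, 4L)
})

test_that("text without lexicon terms yields no mentions", {
  doc <- patent_corpus("X1", "2001-01-01", title = "A network router")
  expect_identical(nrow(recognize(doc, tiny_lexicon())), 0L)
})

test_that("recognition is deterministic, case-insensitive and non-overlapping", {
  doc <- patent_corpus(
    "X1", "2001-01-01",
    title = "Diabetes Mellitus and influenza",
    abstract = "INFLUENZA vaccine for type 2 DIABETES mellitus patients")
  m1 <- recognize(doc, tiny_lexicon())
  m2 <- recognize(doc, tiny_lexicon())
  expect_identical(m1, m2)
  # surfaces preserve original casing of the covered token slice
  expect_true("Diabetes Mellitus" %in% m1$surface)
  # no overlapping spans within a section
  for (sec in unique(m1$section)) {
    s <- m1[m1$section == sec, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
})

test_that("rollup distinguishes definitive and ambiguous mappings", {
  b <- tiny_bundle()
  # one-to-one chain
  r1 <- rollup("C0011860", b)
  expect_identical(r1, list(roots = "250", definitive = TRUE))
  # multiple ICD-9 codes converging on one root is still definitive
  r2 <- rollup("C0011849", b)
  expect_identical(r2, list(roots = "250", definitive = TRUE))
  # diverging roots are ambiguous
  r3 <- rollup("C0021400", b)
  expect_identical(r3$roots, c("481", "482"))
  expect_false(r3$definitive)
  # absent CUI
  expect_identical(rollup("C9999999", b),
                   list(roots = character(0), definitive = FALSE))
})

test_that("rollup is invariant to mapping-table row order", {
  b <- tiny_bundle()
  shuffled <- mapping_bundle(
    b$cui_to_icd9[rev(seq_len(nrow(b$cui_to_icd9))), ],
    b$icd9_to_phecode[c(3, 1, 4, 2), ],
    b$phecode_to_root[sample(seq_len(nrow(b$phecode_to_root))), ])
  for (cui in c("C0011860", "C0011849", "C0021400")) {
    expect_identical(rollup(cui, b), rollup(cui, shuffled))
  }
})

test_that("bundle constructor enforces its invariants", {
  b <- tiny_bundle()
  expect_error(mapping_bundle(b$cui_to_icd9,
                              data.frame(source = "250.00", target = "999.9"),
                              b$phecode_to_root),
               "without a root")
  broken_roots <- data.frame(
    source = c("250.2", "481.0", "482.0", "481", "482"),
    target = c("250", "481", "482", "481", "482"))
  # "250" appears as a root but never maps to itself
  expect_error(mapping_bundle(b$cui_to_icd9, b$icd9_to_phecode, broken_roots),
               "map to themselves")
})

test_that("annotation unions roots per document under both policies", {
  corpus <- patent_corpus(
    c("P1", "P2"), "2001-06-01",
    title = c("Treating diabetes mellitus and influenza",
              "A fuel injector"))
  ann_all <- annotate_corpus(corpus, tiny_lexicon(), tiny_bundle(), "all")
  expect_identical(ann_all$roots[[1]], c("250", "481", "482"))
  expect_identical(ann_all$roots[[2]], character(0))
  ann_drop <- annotate_corpus(corpus, tiny_lexicon(), tiny_bundle(), "drop")
  expect_identical(ann_drop$roots[[1]], "250")
  # "drop" root sets are always subsets of "all" root sets
  expect_true(all(mapply(function(d, a) all(d %in% a),
                         ann_drop$roots, ann_all$roots)))
})

test_that("mapping audit reports definitive/ambiguous percentages that sum", {
  b <- tiny_bundle()
  a <- mapping_audit(b, c("C0011860", "C0011849", "C0021400", "C404"))
  expect_identical(a$n_definitive, 2L)
  expect_identical(a$n_ambiguous, 1L)
  expect_identical(a$n_unmapped, 1L)
  expect_equal(a$definitive_pct + a$ambiguous_pct, 100)
  expect_equal(a$definitive_pct, 100 * 2 / 3)

  all_unmapped <- mapping_audit(b, c("C1", "C2"))
  expect_true(is.na(all_unmapped$definitive_pct))
  expect_identical(all_unmapped$n_unmapped, 2L)
  expect_error(mapping_audit(b, character(0)), "non-empty")
})

test_that("a 9-definitive / 1-ambiguous table audits at 90%", {
  cfg <- synth_config(seed = 3, n_diseases = 10, ambiguity_fraction = 0.1)
  lm10 <- make_lexicon_and_mappings(cfg)
  a <- mapping_audit(lm10$bundle, lm10$truth$cui)
  expect_equal(a$definitive_pct, 90)
})

test_that("annotations round-trip through the TSV export", {
  corpus <- patent_corpus(
    c("P1", "P2"), "2001-06-01",
    title = c("Treating diabetes mellitus and influenza", "A fuel injector"))
  ann <- annotate_corpus(corpus, tiny_lexicon(), tiny_bundle())
  path <- withr::local_tempfile()
  write_annotations(ann, path)
  got <- read_annotations(path)
  expect_equal(got[order(got$doc_id), ], ann[order(ann$doc_id), ],
               ignore_attr = TRUE)
})

test_that("icd10 bridging uses the optional extra table", {
  b <- tiny_bundle()
  expect_error(bridge_icd10("E11.9", b), "no icd10_to_icd9")
  b2 <- mapping_bundle(b$cui_to_icd9, b$icd9_to_phecode, b$phecode_to_root,
                       icd10_to_icd9 = data.frame(source = "E11.9",
                                                  target = "250.00"))
  expect_identical(bridge_icd10(c("E11.9", "Z99"), b2),
                   list("250.00", character(0)))
})
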