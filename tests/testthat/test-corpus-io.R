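test_that("both dialects read well-formed records in file order", {
  corpus <- tiny_corpus()
  for (dialect in c("xml", "records")) {
    path <- withr::local_tempfile(fileext = if (dialect == "xml") ".xml"
                                  else ".jsonl")
    write_corpus(corpus, path, dialect)
    got <- read_corpus(path, dialect)
    expect_identical(got$doc_id, corpus$doc_id)
    expect_identical(attr(got, "n_skipped"), 0L)
  }
})

test_that("malformed records are skipped and counted, not fatal", {
  lines <- c(
    '{"doc_number":"A1","date":"20000101","title":"t","abstract":"a","claims":"","uspc":[],"cpc":["A61K"]}',
    '{"doc_number":"A2","title":"missing date","abstract":"a","claims":"","uspc":[],"cpc":[]}',
    '{"doc_number":"A3","date":"20010101","title":"t","abstract":"a","claims":"","uspc":[],"cpc":[]}'
  )
  path <- withr::local_tempfile()
  writeLines(lines, path)
  expect_warning(got <- read_corpus(path, "records"), "skipped")
  expect_identical(got$doc_id, c("A1", "A3"))
  expect_identical(attr(got, "n_skipped"), 1L)
})

test_that("a file with no parseable record is an explicit empty-corpus error", {
  path <- withr::local_tempfile()
  writeLines('{"title":"no id"}', path)
  expect_error(suppressWarnings(read_corpus(path, "records")),
               "empty corpus")
  expect_error(read_corpus(file.path(tempdir(), "nope.xml"), "xml"),
               "cannot read")
})

test_that("write/read round-trip is field-identical on synthetic corpora", {
  cfg <- synth_config(seed = 11, docs_per_year = 20, years = 2001:2002)
  sim <- make_corpus(cfg, make_lexicon_and_mappings(cfg))
  for (dialect in c("xml", "records")) {
    path <- withr::local_tempfile()
    write_corpus(sim$corpus, path, dialect)
    got <- read_corpus(path, dialect)
    attr(got, "n_skipped") <- NULL
    expect_equal(tibble::as_tibble(got), tibble::as_tibble(sim$corpus))
  }
})

test_that("is_biomedical applies the inclusive date window and code match", {
  corpus <- tiny_corpus()
  crit <- tiny_criteria()
  flags <- is_biomedical(corpus, crit)
  # D1 is dated 1994-12-31, one day before the window opens
  expect_false(flags[[1]])
  expect_true(all(flags[2:5] == c(TRUE, FALSE, TRUE, TRUE)))

  exact <- filter_criteria(uspc_allowlist = "600", cpc_allowlist = "A61K",
                           match_mode = "exact")
  # "A61K31/00" only matches the "A61K" pattern under prefix mode
  one <- corpus[2, ]
  expect_false(is_biomedical(one, exact))
  prefix <- filter_criteria(uspc_allowlist = "600", cpc_allowlist = "A61K",
                            match_mode = "prefix")
  expect_true(is_biomedical(one, prefix))
})

test_that("documents with unparseable grant dates are rejected with warning", {
  corpus <- tiny_corpus()
  corpus$grant_date[2] <- NA
  expect_warning(flags <- is_biomedical(corpus, tiny_criteria()),
                 "unparseable")
  expect_false(flags[[2]])
})

test_that("filter_corpus output, report and invariants reconcile", {
  corpus <- tiny_corpus()
  crit <- tiny_criteria()
  res <- filter_corpus(corpus, crit)
  expect_identical(res$corpus$doc_id, c("D2", "D4", "D5"))
  r <- res$report
  expect_identical(r$n_total, 5L)
  expect_identical(r$n_biomedical, nrow(res$corpus))
  expect_lte(r$n_biomedical, min(r$n_pass_date, r$n_pass_code))
  expect_true(all(r$per_year$biomedical <= r$per_year$total))

  # idempotence: filtering a filtered corpus changes nothing
  res2 <- filter_corpus(res$corpus, crit)
  expect_identical(tibble::as_tibble(res2$corpus),
                   tibble::as_tibble(res$corpus))
  expect_identical(res2$report$n_biomedical, r$n_biomedical)

  # all-pass criteria: output equals input
  all_pass <- filter_criteria(date_start = "1990-01-01",
                              date_end = "2020-01-01",
                              uspc_allowlist = c("600", "607", "709"),
                              cpc_allowlist = c("A61", "H04"),
                              match_mode = "prefix")
  expect_identical(filter_corpus(corpus, all_pass)$corpus$doc_id,
                   corpus$doc_id)
})

test_that("criteria constructor rejects invalid windows and empty allowlists", {
  expect_error(filter_criteria(date_start = "2001-01-01",
                               date_end = "2000-01-01",
                               cpc_allowlist = "A61K"),
               "date_start")
  expect_error(filter_criteria(), "allowlist")
})
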