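#' Synthetic-study generator configuration
#'
#' Bundles every knob of the synthetic data that the pipeline's recovery
#' tests run on: corpus shape (years, documents per year, tokens per
#' document), the disease layer (number of diseases, per-document mention
#' probabilities, the fraction of CUIs wired to two root PheCodes, the
#' fraction of biomedical documents), the planted topic layer (number of
#' topics, filler vocabulary size, optional keyword drift schedule) and the
#' measure layer (per-disease fold-imbalances between burden share and
#' resource share, per-measure totals, noise model).
#'
#' @param seed Integer seed; every byte of generator output is a
#'   deterministic function of the config including the seed.
#' @param years Ordered integer vector of grant years (one time slice each).
#' @param docs_per_year Documents generated per year.
#' @param n_diseases Number of synthetic diseases (>= 2).
#' @param mention_prob Per-document probability that a disease's surface
#'   term is inserted; scalar or length-`n_diseases` vector.
#' @param ambiguity_fraction Fraction of disease CUIs mapped to two root
#'   PheCodes through divergent ICD-9 codes (in \[0, 1\]).
#' @param biomedical_fraction Fraction of documents given an allowlisted
#'   classification code and an in-window date; the rest get an off-list
#'   code or an out-of-window date (filter bait).
#' @param tokens_per_doc Filler tokens drawn per document from the planted
#'   topic distributions.
#' @param topics List: `K_true` (planted topic count), `vocab_size` (filler
#'   vocabulary), optional `drift` (list with `topic`, `term`, `start`,
#'   `end`: that term's planted probability ramps linearly across slices).
#' @param measure_spec List: `folds` (length-`n_diseases` vector or
#'   diseases x years matrix of planted burden/resource fold ratios
#'   \eqn{\rho_d = X_{bd}/R_d}), `totals` (named vector over b, r, c, p),
#'   `noise` (`"none"` or `"poisson"`), `lognormal_sd` (> 0 applies
#'   multiplicative log-normal noise to the burden measure instead of
#'   Poisson), `resource_spread` (decorrelates the three resource measures
#'   around the composite without moving the equal-weight composite).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         years = 2000:2002,
                         docs_per_year = 200L,
                         n_diseases = 8L,
                         mention_prob = 0.3,
                         ambiguity_fraction = 0,
                         biomedical_fraction = 0.6,
                         tokens_per_doc = 40L,
                         topics = list(K_true = 3L, vocab_size = 60L,
                                       drift = NULL),
                         measure_spec = list(
                           folds = NULL, totals = c(b = 1e4, r = 1e4,
                                                    c = 1e4, p = 1e4),
                           noise = "none", lognormal_sd = 0)) {
  stopifnot(n_diseases >= 2, docs_per_year >= 1, length(years) >= 1)
  if (ambiguity_fraction < 0 || ambiguity_fraction > 1) {
    stop("ambiguity_fraction must be in [0, 1]")
  }
  if (length(mention_prob) == 1L) {
    mention_prob <- rep(mention_prob, n_diseases)
  }
  stopifnot(length(mention_prob) == n_diseases,
            all(mention_prob >= 0), all(mention_prob <= 1))
  if (is.null(topics$K_true)) topics$K_true <- 3L
  if (is.null(topics$vocab_size)) topics$vocab_size <- 60L
  if (is.null(measure_spec$totals)) {
    measure_spec$totals <- c(b = 1e4, r = 1e4, c = 1e4, p = 1e4)
  }
  if (is.null(measure_spec$noise)) measure_spec$noise <- "none"
  if (is.null(measure_spec$lognormal_sd)) measure_spec$lognormal_sd <- 0
  if (is.null(measure_spec$resource_spread)) measure_spec$resource_spread <- 0
  if (is.null(measure_spec$folds)) {
    # default: half understudied, half overstudied, straddling 1 so the
    # planted shares can renormalize
    f <- rep(c(2, 0.5), length.out = n_diseases)
    measure_spec$folds <- f
  }
  structure(
    list(seed = as.integer(seed), years = as.integer(years),
         docs_per_year = as.integer(docs_per_year),
         n_diseases = as.integer(n_diseases), mention_prob = mention_prob,
         ambiguity_fraction = ambiguity_fraction,
         biomedical_fraction = biomedical_fraction,
         tokens_per_doc = as.integer(tokens_per_doc),
         topics = topics, measure_spec = measure_spec),
    class = "synth_config"
  )
}

#' Demo preset
#'
#' A small configuration (3 years x 200 documents x 8 diseases x 3 planted
#' topics) that runs the full pipeline end-to-end in well under a minute.
#'
#' @param seed Integer seed.
#' @return A [synth_config()].
#' @export
synth_preset_demo <- function(seed = 1L) {
  synth_config(seed = seed,
               measure_spec = list(
                 folds = rep(c(3, 2, 1, 0.5), length.out = 8),
                 totals = c(b = 1e4, r = 1e4, c = 1e4, p = 1e4),
                 noise = "poisson", lognormal_sd = 0,
                 resource_spread = 0.6))
}

# Deterministic letter-string name for disease i ("xaa", "xab", ...,
# base-26, arbitrarily many letters).
.disease_word <- function(i) {
  out <- ""
  while (i > 0L) {
    i <- i - 1L
    out <- paste0(letters[i %% 26L + 1L], out)
    i <- i %/% 26L
  }
  paste0("x", out)
}

#' Generate the disease lexicon and mapping tables
#'
#' One unique multiword surface term per disease CUI ("disorder xaa", ...).
#' The first `round(ambiguity_fraction * n_diseases)` CUIs are wired to two
#' root PheCodes through divergent ICD-9 codes; the rest roll up
#' one-to-one. Roots map to themselves.
#'
#' @param config A [synth_config()].
#' @return List with `lexicon`, `bundle`, and `truth` (tibble: `disease`,
#'   `cui`, `term`, `root`, `ambiguous`, `extra_root`).
#' @export
make_lexicon_and_mappings <- function(config) {
  n <- config$n_diseases
  i <- seq_len(n)
  cui <- sprintf("C%07d", i)
  term <- paste("disorder", vapply(i, .disease_word, character(1)))
  root <- sprintf("%03d", i)
  n_amb <- round(config$ambiguity_fraction * n)
  ambiguous <- i <= n_amb
  extra_root <- ifelse(ambiguous, sprintf("8%02d", i %% 100), NA_character_)

  cui_to_icd9 <- tibble::tibble(
    source = c(cui, cui[ambiguous]),
    target = c(sprintf("I9.%03d.a", i), sprintf("I9.%03d.b", i[ambiguous])))
  icd9_to_phecode <- tibble::tibble(
    source = cui_to_icd9$target,
    target = c(sprintf("%03d.1", i), sprintf("8%02d.1", i[ambiguous] %% 100)))
  phe_child <- unique(icd9_to_phecode$target)
  child_root <- c(stats::setNames(root, sprintf("%03d.1", i)),
                  stats::setNames(extra_root[ambiguous],
                                  sprintf("8%02d.1", i[ambiguous] %% 100)))
  all_roots <- unique(c(root, extra_root[ambiguous]))
  phecode_to_root <- tibble::tibble(
    source = c(phe_child, all_roots),
    target = c(unname(child_root[phe_child]), all_roots))

  list(
    lexicon = lexicon(term, cui),
    bundle = mapping_bundle(cui_to_icd9, icd9_to_phecode, phecode_to_root),
    truth = tibble::tibble(disease = i, cui = cui, term = term, root = root,
                           ambiguous = ambiguous, extra_root = extra_root)
  )
}

# Planted per-slice topic-term distributions: disjoint vocabulary blocks
# per topic with a within-block Zipf profile; optional linear keyword ramp.
.planted_topics <- function(config) {
  K <- config$topics$K_true
  V <- config$topics$vocab_size
  Tn <- length(config$years)
  vocab <- sprintf("w%03d", seq_len(V))
  block <- rep(seq_len(K), length.out = V)
  beta1 <- matrix(0, K, V, dimnames = list(NULL, vocab))
  for (k in seq_len(K)) {
    idx <- which(block == k)
    p <- 1 / seq_along(idx)
    beta1[k, idx] <- p / sum(p)
  }
  beta <- lapply(seq_len(Tn), function(t) beta1)
  drift <- config$topics$drift
  if (!is.null(drift)) {
    path <- seq(drift$start, drift$end, length.out = Tn)
    for (t in seq_len(Tn)) {
      b <- beta[[t]]
      k <- drift$topic
      v <- drift$term
      rest <- setdiff(seq_len(V), v)
      b[k, rest] <- b[k, rest] * (1 - path[t]) / sum(b[k, rest])
      b[k, v] <- path[t]
      beta[[t]] <- b
    }
  }
  list(beta = beta, vocab = vocab)
}

#' Generate a synthetic patent corpus
#'
#' Documents are filler tokens sampled from the planted per-slice topic
#' distributions (one planted topic per document, drawn uniformly), with
#' each disease's surface term inserted independently with its mention
#' probability. A `biomedical_fraction` of documents receive an allowlisted
#' CPC code and an in-window grant date; the remainder get either an
#' off-list code or an out-of-window date, as filter bait.
#'
#' @param config A [synth_config()].
#' @param lexmap Output of [make_lexicon_and_mappings()] for the same
#'   config.
#' @return List with `corpus` (a `patent_corpus`), `criteria` (the
#'   [filter_criteria()] matching the planted window and codes) and `truth`
#'   (list: `docs` tibble with per-document planted year, biomedical flag,
#'   topic and disease roots; `incidence` tibble of planted per-disease-year
#'   biomedical document counts; `beta` planted per-slice topic matrices;
#'   `vocab`).
#' @export
make_corpus <- function(config, lexmap) {
  set.seed(config$seed)
  planted <- .planted_topics(config)
  Tn <- length(config$years)
  n_total <- Tn * config$docs_per_year
  disease_terms <- lexmap$truth$term
  disease_roots <- lexmap$truth$root

  rows <- vector("list", n_total)
  doc_meta <- vector("list", n_total)
  idx <- 0L
  for (t in seq_len(Tn)) {
    year <- config$years[[t]]
    for (j in seq_len(config$docs_per_year)) {
      idx <- idx + 1L
      doc_id <- sprintf("US%07d", idx)
      topic <- sample.int(config$topics$K_true, 1L)
      toks <- sample(planted$vocab, config$tokens_per_doc, replace = TRUE,
                     prob = planted$beta[[t]][topic, ])
      mentioned <- which(stats::runif(config$n_diseases) <
                           config$mention_prob)
      if (length(mentioned) > 0) {
        # insert whole terms at filler-token boundaries so one planted
        # mention can never split another
        pos <- sample.int(length(toks) + 1L, length(mentioned),
                          replace = TRUE) - 1L
        for (ord in order(pos, decreasing = TRUE)) {
          toks <- append(toks, strsplit(disease_terms[[mentioned[ord]]],
                                        " ")[[1]],
                         after = pos[ord])
        }
      }
      biomedical <- stats::runif(1) < config$biomedical_fraction
      if (biomedical) {
        date <- as.Date(sprintf("%d-%02d-%02d", year,
                                sample.int(12, 1), sample.int(28, 1)))
        cpc <- "A61K31/00"
      } else if (stats::runif(1) < 0.5) {
        # in window, off-list code
        date <- as.Date(sprintf("%d-%02d-%02d", year,
                                sample.int(12, 1), sample.int(28, 1)))
        cpc <- "H04L9/00"
      } else {
        # allowlisted code, dated before the window
        date <- as.Date(sprintf("%d-%02d-%02d", min(config$years) - 2L,
                                sample.int(12, 1), sample.int(28, 1)))
        cpc <- "A61K31/00"
      }
      rows[[idx]] <- list(doc_id = doc_id, grant_date = date,
                          abstract = paste(toks, collapse = " "),
                          cpc = cpc)
      doc_meta[[idx]] <- tibble::tibble(
        doc_id = doc_id, year = year, biomedical = biomedical,
        topic = topic, roots = list(sort(disease_roots[mentioned])))
    }
  }
  corpus <- patent_corpus(
    doc_id = vapply(rows, `[[`, character(1), "doc_id"),
    grant_date = as.Date(vapply(rows, function(r)
      as.character(r$grant_date), character(1))),
    title = "", abstract = vapply(rows, `[[`, character(1), "abstract"),
    claims = "",
    uspc = rep(list(character(0)), n_total),
    cpc = lapply(rows, function(r) r$cpc))
  docs <- dplyr::bind_rows(doc_meta)
  incidence <- docs |>
    dplyr::filter(.data$biomedical) |>
    tidyr::unnest("roots") |>
    dplyr::count(root = .data$roots, year = .data$year, name = "n_docs")
  criteria <- filter_criteria(
    date_start = sprintf("%d-01-01", min(config$years)),
    date_end = sprintf("%d-12-31", max(config$years)),
    cpc_allowlist = "A61K", match_mode = "prefix")
  list(corpus = corpus, criteria = criteria,
       truth = list(docs = docs, incidence = incidence,
                    beta = planted$beta, vocab = planted$vocab))
}

# Solve for base resource shares R with sum(R) = 1 and sum(f * R) = 1,
# given planted folds f (R_d proportional to exp(-c * f_d), c by uniroot).
.solve_base_shares <- function(f) {
  if (all(abs(f - 1) < 1e-12)) return(rep(1 / length(f), length(f)))
  if (min(f) >= 1 || max(f) <= 1) {
    stop("infeasible fold pattern: folds must straddle 1 so burden and ",
         "resource shares can both normalize (got range [",
         signif(min(f), 3), ", ", signif(max(f), 3), "])")
  }
  g <- function(c) {
    w <- exp(-c * (f - min(f)))
    sum(f * w) / sum(w) - 1
  }
  c_star <- stats::uniroot(g, c(-200, 200), tol = 1e-14)$root
  w <- exp(-c_star * (f - min(f)))
  w / sum(w)
}

#' Generate synthetic measure tables with planted fold-imbalances
#'
#' Constructs true shares per year such that the burden share equals the
#' planted fold times the composite resource share,
#' \eqn{X^*_{bd} = f_d R^*_d}, with both sides normalizing to 1 (the three
#' resource measures all receive \eqn{R^*_d}, so the composite equals
#' \eqn{R^*_d} under any weights summing to 1). Shares are scaled by the
#' per-measure totals and optionally degraded with Poisson (counts) or
#' log-normal (burden cost) noise.
#'
#' @param config A [synth_config()] whose `measure_spec` is valid.
#' @return List with `measures` (a noisy [measure_table()]),
#'   `measures_true` (the noiseless one), and `truth` (tibble: `disease`,
#'   `phecode`, `year`, `fold`, `R_true`, `X_b_true`, `expected_roi`).
#' @export
make_measures <- function(config) {
  set.seed(config$seed + 1L)
  spec <- config$measure_spec
  n <- config$n_diseases
  years <- config$years
  folds <- spec$folds
  if (is.null(dim(folds))) {
    folds <- matrix(folds, nrow = n, ncol = length(years))
  }
  stopifnot(nrow(folds) == n, ncol(folds) == length(years))
  phecode <- sprintf("%03d", seq_len(n))

  truth_rows <- list()
  raw_rows <- list()
  true_rows <- list()
  for (ti in seq_along(years)) {
    f <- folds[, ti]
    R <- .solve_base_shares(f)
    X_b <- f * R
    # spread the three resource measures around R without moving the
    # equal-weight composite: transfer share within consecutive disease
    # pairs (r gains where c loses and vice versa), so every measure still
    # normalizes, stays nonnegative, and (X_r + X_c + X_p)/3 = R exactly
    delta <- numeric(n)
    if (spec$resource_spread > 0 && n >= 2) {
      for (d in seq(1, n - 1, by = 2)) {
        amt <- spec$resource_spread * min(R[d], R[d + 1]) / 2
        delta[d] <- amt
        delta[d + 1] <- -amt
      }
    }
    shares <- list(b = X_b, r = R + delta, c = R - delta, p = R)
    for (m in names(shares)) {
      lam <- shares[[m]] * spec$totals[[m]]
      value <- if (spec$noise == "poisson") {
        if (m == "b" && spec$lognormal_sd > 0) {
          lam * exp(stats::rnorm(n, 0, spec$lognormal_sd))
        } else {
          stats::rpois(n, lam)
        }
      } else lam
      raw_rows[[length(raw_rows) + 1L]] <- tibble::tibble(
        measure = m, phecode = phecode, year = years[[ti]], value = value)
      true_rows[[length(true_rows) + 1L]] <- tibble::tibble(
        measure = m, phecode = phecode, year = years[[ti]], value = lam)
    }
    truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
      disease = seq_len(n), phecode = phecode, year = years[[ti]],
      fold = f, R_true = R, X_b_true = X_b,
      expected_roi = ifelse(f >= 1, f, -1 / f))
  }
  raw <- dplyr::bind_rows(raw_rows)
  true_tab <- dplyr::bind_rows(true_rows)
  list(
    measures = measure_table(raw$measure, raw$phecode, raw$year, raw$value),
    measures_true = measure_table(true_tab$measure, true_tab$phecode,
                                  true_tab$year, true_tab$value),
    truth = dplyr::bind_rows(truth_rows)
  )
}

#' Write a full synthetic study to disk
#'
#' Materializes everything the pipeline consumes as real files in the
#' external formats (corpus, lexicon, mapping tables, measure tables) plus
#' the ground truth as JSON, so I/O code is exercised by every recovery
#' test. Byte-identical across reruns with the same config.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created).
#' @param dialect Corpus dialect, `"records"` or `"xml"`.
#' @return Invisibly, a list with `paths` (the written files) and the
#'   in-memory objects (`corpus`, `criteria`, `lexicon`, `bundle`,
#'   `measures`, `measures_true`, `truth`).
#' @export
simulate_study <- function(config, dir, dialect = c("records", "xml")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lexmap <- make_lexicon_and_mappings(config)
  corp <- make_corpus(config, lexmap)
  meas <- make_measures(config)

  paths <- list(
    corpus = file.path(dir, if (dialect == "xml") "corpus.xml"
                            else "corpus.jsonl"),
    lexicon = file.path(dir, "lexicon.tsv"),
    cui_to_icd9 = file.path(dir, "cui_to_icd9.tsv"),
    icd9_to_phecode = file.path(dir, "icd9_to_phecode.tsv"),
    phecode_to_root = file.path(dir, "phecode_to_root.tsv"),
    measures = file.path(dir, "measures.csv"),
    measures_true = file.path(dir, "measures_true.csv"),
    ground_truth = file.path(dir, "ground_truth.json"))

  write_corpus(corp$corpus, paths$corpus, dialect)
  write_lexicon(lexmap$lexicon, paths$lexicon)
  write_mapping_table(lexmap$bundle$cui_to_icd9, paths$cui_to_icd9)
  write_mapping_table(lexmap$bundle$icd9_to_phecode, paths$icd9_to_phecode)
  write_mapping_table(lexmap$bundle$phecode_to_root, paths$phecode_to_root)
  write_measures(meas$measures, paths$measures)
  write_measures(meas$measures_true, paths$measures_true)

  truth <- list(
    config = unclass(config),
    diseases = lexmap$truth,
    docs = corp$truth$docs |>
      dplyr::mutate(roots = vapply(.data$roots, paste, character(1),
                                   collapse = ";")),
    incidence = corp$truth$incidence,
    measures = meas$truth)
  jsonlite::write_json(truth, paths$ground_truth, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(paths = paths, corpus = corp$corpus,
                 criteria = corp$criteria, lexicon = lexmap$lexicon,
                 bundle = lexmap$bundle, measures = meas$measures,
                 measures_true = meas$measures_true,
                 truth = list(lexmap = lexmap$truth, corpus = corp$truth,
                              measures = meas$truth)))
}
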