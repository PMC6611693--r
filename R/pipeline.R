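#' Validate a pipeline configuration
#'
#' A run configuration is a declarative YAML file (or an equivalent named
#' list): input paths for the corpus, lexicon, mapping tables and measure
#' tables, the filter criteria, ambiguity policy, index weights and window,
#' topic-model settings and seeds, and the output directory. Validation
#' collects *all* problems and reports them together rather than stopping
#' at the first.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The validated config (class `run_config`), or an error of class
#'   `config_error` whose message lists every problem.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(yaml::read_yaml(config), error = function(e) {
      stop(structure(class = c("config_error", "error", "condition"),
                     list(message = paste("unparseable config file:",
                                          conditionMessage(e)),
                          call = NULL)))
    })
  }
  errors <- character(0)
  need_path <- function(x, name) {
    if (is.null(x)) {
      errors <<- c(errors, paste0("missing required path: ", name))
    } else if (!file.exists(x)) {
      errors <<- c(errors, paste0(name, " does not exist: ", x))
    }
  }
  need_path(config$corpus$path, "corpus.path")
  need_path(config$lexicon, "lexicon")
  need_path(config$mappings$cui_to_icd9, "mappings.cui_to_icd9")
  need_path(config$mappings$icd9_to_phecode, "mappings.icd9_to_phecode")
  need_path(config$mappings$phecode_to_root, "mappings.phecode_to_root")
  need_path(config$measures, "measures")
  if (is.null(config$out_dir)) {
    errors <- c(errors, "missing required field: out_dir")
  }
  dialect <- config$corpus$dialect %||% "records"
  if (!dialect %in% c("records", "xml")) {
    errors <- c(errors, paste0("corpus.dialect must be records or xml, got ",
                               dialect))
  }
  filt <- config$filter
  if (!is.null(filt$date_start) && !is.null(filt$date_end)) {
    ds <- tryCatch(as.Date(filt$date_start), error = function(e) NA)
    de <- tryCatch(as.Date(filt$date_end), error = function(e) NA)
    if (is.na(ds) || is.na(de)) {
      errors <- c(errors, "filter dates must be YYYY-MM-DD")
    } else if (ds > de) {
      errors <- c(errors, "filter.date_start is after filter.date_end")
    }
  }
  if (!is.null(config$window)) {
    if (config$window$start > config$window$end) {
      errors <- c(errors, "window.start is after window.end")
    }
  }
  w <- config$weights
  if (!is.null(w)) {
    wv <- unlist(w[c("r", "c", "p")])
    if (length(wv) != 3 || any(is.na(wv)) || any(wv < 0) ||
        abs(sum(wv) - 1) > 1e-9) {
      errors <- c(errors,
                  "weights must give nonnegative r, c, p summing to 1")
    }
  }
  policy <- config$ambiguity_policy %||% "all"
  if (!policy %in% c("all", "drop")) {
    errors <- c(errors, "ambiguity_policy must be 'all' or 'drop'")
  }
  if (length(errors) > 0) {
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = paste0("invalid configuration:\n  - ",
                                         paste(errors, collapse = "\n  - ")),
                        call = NULL)))
  }
  structure(config, class = c("run_config", class(config)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the five stages in order - filter, annotate, coverage, indices,
#' topics - each stage reading only the previous stage's declared outputs,
#' and writes every table under the configured output directory. A run
#' manifest (config snapshot, package version, per-stage row counts,
#' timestamps, warnings) is written even when a stage fails, with the
#' failed stage and cause recorded. Reruns with identical config and seeds
#' reproduce identical data outputs.
#'
#' @param config A config accepted by [validate_config()].
#' @return The manifest, invisibly (list of class `run_manifest`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("patentscape")),
    config = unclass(config),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(), warnings = character(0), failed_stage = NULL)
  note <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  finish <- function() {
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  }
  stage <- function(name, fun) {
    res <- tryCatch(withCallingHandlers(fun(), warning = note),
                    error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed_stage <<- list(stage = name,
                                     cause = conditionMessage(res))
      finish()
      stop("pipeline failed at stage '", name, "': ",
           conditionMessage(res), call. = FALSE)
    }
    res
  }

  # -- filter ---------------------------------------------------------------
  filtered <- stage("filter", function() {
    corpus <- read_corpus(config$corpus$path,
                          config$corpus$dialect %||% "records")
    filt <- config$filter %||% list()
    criteria <- filter_criteria(
      date_start = filt$date_start %||% "1995-01-01",
      date_end = filt$date_end %||% "2017-12-31",
      uspc_allowlist = unlist(filt$uspc_allowlist) %||% character(0),
      cpc_allowlist = unlist(filt$cpc_allowlist) %||%
        default_code_allowlist()$cpc,
      match_mode = filt$match_mode %||% "prefix")
    res <- filter_corpus(corpus, criteria)
    write_corpus(res$corpus, file.path(out_dir, "filtered.jsonl"), "records")
    write_filter_report(res$report, file.path(out_dir, "filter_report.csv"))
    res
  })
  manifest$stages$filter <- list(n_in = filtered$report$n_total,
                                 n_out = filtered$report$n_biomedical)

  # -- annotate -------------------------------------------------------------
  ann <- stage("annotate", function() {
    lex <- read_lexicon(config$lexicon)
    bundle <- mapping_bundle(
      read_mapping_table(config$mappings$cui_to_icd9),
      read_mapping_table(config$mappings$icd9_to_phecode),
      read_mapping_table(config$mappings$phecode_to_root))
    annotations <- annotate_corpus(filtered$corpus, lex, bundle,
                                   config$ambiguity_policy %||% "all")
    write_annotations(annotations, file.path(out_dir, "annotations.tsv"))
    audit <- mapping_audit(bundle, lex$cui)
    jsonlite::write_json(unclass(audit),
                         file.path(out_dir, "mapping_audit.json"),
                         auto_unbox = TRUE, digits = NA)
    list(annotations = annotations, lex = lex, bundle = bundle)
  })
  manifest$stages$annotate <- list(
    n_docs = nrow(ann$annotations),
    n_annotated = sum(vapply(ann$annotations$roots, length, integer(1)) > 0))

  # -- coverage -------------------------------------------------------------
  cov_mat <- stage("coverage", function() {
    years <- stats::setNames(
      as.integer(format(filtered$corpus$grant_date, "%Y")),
      filtered$corpus$doc_id)
    mat <- tabulate_disease_year(ann$annotations, years)
    write_coverage_tables(mat, out_dir,
                          k = config$coverage$top_k %||% 24)
    mat
  })
  manifest$stages$coverage <- list(n_diseases = nrow(cov_mat$counts),
                                   n_years = ncol(cov_mat$counts))

  # -- indices --------------------------------------------------------------
  X <- stage("indices", function() {
    measures <- read_measures(config$measures)
    if (!is.null(config$window)) {
      measures <- measures[measures$year >= config$window$start &
                           measures$year <= config$window$end, ]
    }
    X <- normalize_measures(measures)
    w <- config$weights
    weights <- if (is.null(w)) c(r = 1/3, c = 1/3, p = 1/3)
               else c(r = w$r, c = w$c, p = w$p)
    write_index_tables(X, out_dir, weights)
    X
  })
  manifest$stages$indices <- list(n_rows = nrow(X))

  # -- topics ---------------------------------------------------------------
  tp <- config$topics %||% list()
  fit <- stage("topics", function() {
    sub <- filtered$corpus
    if (!is.null(tp$phecode)) {
      keep <- vapply(ann$annotations$roots, function(r)
        tp$phecode %in% r, logical(1))
      sub <- sub[sub$doc_id %in% ann$annotations$doc_id[keep], ]
    }
    tok <- preprocess_corpus(sub, ann$lex)
    dtm <- build_matrix(tok, min_df = tp$min_df %||% 2L)
    write_matrix(dtm, file.path(out_dir, "dtm"))
    params <- dtm_params(K = tp$k %||% 10L, alpha = tp$alpha %||% 0.01,
                         sigma = tp$sigma %||% 0.005,
                         n_iter = tp$n_iter %||% 60L,
                         seed = tp$seed %||% 1L)
    fit <- if (!is.null(tp$grid)) {
      sel <- select_topic_number(dtm, grid = unlist(tp$grid),
                                 params = params,
                                 seeds_per_k = tp$seeds_per_k %||% 1L)
      utils::write.csv(sel$curve, file.path(out_dir, "coherence_curve.csv"),
                       row.names = FALSE)
      params$K <- sel$best_k
      fit_dtm(dtm, params)
    } else {
      fit_dtm(dtm, params)
    }
    write_top_words(fit, file.path(out_dir, "top_words.csv"),
                    n = tp$top_n %||% 10)
    coh <- umass_coherence(fit, dtm, top_n = tp$top_n %||% 10)
    utils::write.csv(
      data.frame(topic = seq_along(coh$per_topic),
                 coherence = coh$per_topic),
      file.path(out_dir, "coherence.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(doc_id = fit$doc_ids, fit$theta),
      file.path(out_dir, "theta.csv"), row.names = FALSE)
    fit
  })
  manifest$stages$topics <- list(K = fit$params$K,
                                 n_docs = nrow(fit$theta),
                                 n_slices = length(fit$slice_years),
                                 converged = fit$converged)

  finish()
  manifest <- structure(manifest, class = "run_manifest")
  invisible(manifest)
}
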