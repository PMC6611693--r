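#' Patent corpus container
#'
#' A patent corpus is a tibble with one row per granted patent:
#' `doc_id` (character, unique), `grant_date` (Date), `title`, `abstract`,
#' `claims` (character, possibly empty), and `uspc` / `cpc` (list columns of
#' character classification codes, possibly empty). Helper constructor that
#' validates the invariants.
#'
#' @param doc_id Character vector of unique, non-empty identifiers.
#' @param grant_date Date vector (or character coercible via `as.Date`).
#' @param title,abstract,claims Character vectors; at least one of the three
#'   must be non-empty for each document.
#' @param uspc,cpc Lists of character vectors of classification codes.
#' @return A tibble of class `patent_corpus`.
#' @export
patent_corpus <- function(doc_id, grant_date, title = "", abstract = "",
                          claims = "", uspc = list(character(0)),
                          cpc = list(character(0))) {
  n <- length(doc_id)
  stopifnot(n > 0)
  if (anyDuplicated(doc_id)) stop("doc_id values must be unique")
  if (any(!nzchar(doc_id))) stop("doc_id values must be non-empty")
  recycle <- function(x) if (length(x) == 1L) rep(x, n) else x
  if (!inherits(grant_date, "Date")) grant_date <- as.Date(grant_date)
  out <- tibble::tibble(
    doc_id = as.character(doc_id),
    grant_date = recycle(grant_date),
    title = recycle(as.character(title)),
    abstract = recycle(as.character(abstract)),
    claims = recycle(as.character(claims)),
    uspc = if (is.list(uspc) && length(uspc) == 1L && n > 1L)
      rep(uspc, n) else uspc,
    cpc = if (is.list(cpc) && length(cpc) == 1L && n > 1L)
      rep(cpc, n) else cpc
  )
  empty_text <- !nzchar(out$title) & !nzchar(out$abstract) & !nzchar(out$claims)
  if (any(empty_text)) {
    stop("documents with empty title, abstract and claims: ",
         paste(utils::head(out$doc_id[empty_text], 5), collapse = ", "))
  }
  class(out) <- c("patent_corpus", class(out))
  out
}

#' Read a patent corpus
#'
#' Reads one of the two supported input dialects:
#' \describe{
#'   \item{`"xml"`}{Simplified patent XML: a `<patents>` root with one
#'     `<patent>` element per document carrying `doc-number`, `date`
#'     (YYYYMMDD), `title`, `abstract`, `claims` and repeated `uspc`/`cpc`
#'     children.}
#'   \item{`"records"`}{Line-delimited records: one JSON object per line,
#'     UTF-8, with fields `doc_number`, `date` (YYYYMMDD), `title`,
#'     `abstract`, `claims`, `uspc`, `cpc`.}
#' }
#' Malformed records (missing identifier or unparseable date) are skipped
#' with a warning and counted in the `n_skipped` attribute, never fatal.
#' Missing optional sections become empty strings.
#'
#' @param path Path to the corpus file.
#' @param dialect `"xml"` or `"records"`.
#' @return A `patent_corpus` tibble, documents in file order, with attribute
#'   `n_skipped` giving the number of malformed records dropped.
#' @export
read_corpus <- function(path, dialect = c("xml", "records")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read corpus file: ", path)
  raw <- switch(dialect,
    xml = .read_corpus_xml(path),
    records = .read_corpus_records(path)
  )
  if (nrow(raw$docs) == 0L) stop("empty corpus: no parseable records in ", path)
  if (raw$n_skipped > 0L) {
    warning(raw$n_skipped, " malformed record(s) skipped while reading ", path)
  }
  docs <- raw$docs
  class(docs) <- c("patent_corpus", class(docs))
  attr(docs, "n_skipped") <- raw$n_skipped
  docs
}

.parse_yyyymmdd <- function(x) {
  if (is.null(x) || is.na(x) || !grepl("^[0-9]{8}$", x)) return(as.Date(NA))
  d <- as.Date(x, format = "%Y%m%d")
  d
}

.read_corpus_xml <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//patent")
  n_skipped <- 0L
  rows <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    get1 <- function(tag) {
      ch <- xml2::xml_find_first(nd, tag)
      if (inherits(ch, "xml_missing")) "" else xml2::xml_text(ch)
    }
    id <- get1("doc-number")
    date <- .parse_yyyymmdd(get1("date"))
    if (!nzchar(id) || is.na(date)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[i]] <- list(
      doc_id = id, grant_date = date,
      title = get1("title"), abstract = get1("abstract"),
      claims = get1("claims"),
      uspc = list(xml2::xml_text(xml2::xml_find_all(nd, "uspc"))),
      cpc = list(xml2::xml_text(xml2::xml_find_all(nd, "cpc")))
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  list(docs = .rows_to_corpus(rows), n_skipped = n_skipped)
}

.read_corpus_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n_skipped <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
    if (is.null(rec)) {
      n_skipped <- n_skipped + 1L
      next
    }
    id <- rec$doc_number
    date <- .parse_yyyymmdd(rec$date)
    if (is.null(id) || !nzchar(id) || is.na(date)) {
      n_skipped <- n_skipped + 1L
      next
    }
    chr0 <- function(x) if (is.null(x) || length(x) == 0) "" else as.character(x)
    codes <- function(x) if (is.null(x)) character(0) else as.character(x)
    rows[[i]] <- list(
      doc_id = as.character(id), grant_date = date,
      title = chr0(rec$title), abstract = chr0(rec$abstract),
      claims = chr0(rec$claims),
      uspc = list(codes(rec$uspc)), cpc = list(codes(rec$cpc))
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  list(docs = .rows_to_corpus(rows), n_skipped = n_skipped)
}

.rows_to_corpus <- function(rows) {
  if (length(rows) == 0L) {
    return(tibble::tibble(
      doc_id = character(0), grant_date = as.Date(character(0)),
      title = character(0), abstract = character(0), claims = character(0),
      uspc = list(), cpc = list()
    ))
  }
  tibble::tibble(
    doc_id = vapply(rows, `[[`, character(1), "doc_id"),
    grant_date = as.Date(vapply(rows, function(r) as.character(r$grant_date),
                                character(1))),
    title = vapply(rows, `[[`, character(1), "title"),
    abstract = vapply(rows, `[[`, character(1), "abstract"),
    claims = vapply(rows, `[[`, character(1), "claims"),
    uspc = lapply(rows, function(r) r$uspc[[1]]),
    cpc = lapply(rows, function(r) r$cpc[[1]])
  )
}

#' Write a patent corpus
#'
#' Inverse of [read_corpus()]: writes either the simplified patent-XML
#' dialect or the line-delimited JSON record dialect. `read_corpus()` on the
#' written file reproduces the corpus field-for-field.
#'
#' @param corpus A `patent_corpus` tibble.
#' @param path Output file path.
#' @param dialect `"xml"` or `"records"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, dialect = c("xml", "records")) {
  dialect <- match.arg(dialect)
  if (dialect == "records") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(list(
        doc_number = corpus$doc_id[[i]],
        date = format(corpus$grant_date[[i]], "%Y%m%d"),
        title = corpus$title[[i]],
        abstract = corpus$abstract[[i]],
        claims = corpus$claims[[i]],
        uspc = corpus$uspc[[i]],
        cpc = corpus$cpc[[i]]
      ), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    root <- xml2::xml_new_root("patents")
    for (i in seq_len(nrow(corpus))) {
      p <- xml2::xml_add_child(root, "patent")
      xml2::xml_add_child(p, "doc-number", corpus$doc_id[[i]])
      xml2::xml_add_child(p, "date", format(corpus$grant_date[[i]], "%Y%m%d"))
      xml2::xml_add_child(p, "title", corpus$title[[i]])
      xml2::xml_add_child(p, "abstract", corpus$abstract[[i]])
      xml2::xml_add_child(p, "claims", corpus$claims[[i]])
      for (code in corpus$uspc[[i]]) xml2::xml_add_child(p, "uspc", code)
      for (code in corpus$cpc[[i]]) xml2::xml_add_child(p, "cpc", code)
    }
    xml2::write_xml(root, path)
  }
  invisible(path)
}

#' Biomedical inclusion criteria
#'
#' Bundles the grant-date window and the USPC/CPC classification allowlists
#' used to restrict a corpus to biomedicine. A document passes when its
#' grant date falls inside `[date_start, date_end]` (inclusive) and at least
#' one of its USPC or CPC codes matches the union of the two allowlists. In
#' `prefix` mode (the default; CPC codes carry hierarchical subgroup
#' suffixes) a code matches when it starts with an allowlist pattern; in
#' `exact` mode the strings must be equal.
#'
#' @param date_start,date_end Window bounds (Date or `"YYYY-MM-DD"`).
#' @param uspc_allowlist,cpc_allowlist Character vectors of code patterns;
#'   not both empty.
#' @param match_mode `"prefix"` or `"exact"`.
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(date_start = "1995-01-01", date_end = "2017-12-31",
                            uspc_allowlist = character(0),
                            cpc_allowlist = character(0),
                            match_mode = c("prefix", "exact")) {
  match_mode <- match.arg(match_mode)
  date_start <- as.Date(date_start)
  date_end <- as.Date(date_end)
  if (is.na(date_start) || is.na(date_end) || date_start > date_end) {
    stop("invalid date window: date_start must be <= date_end")
  }
  if (length(uspc_allowlist) == 0 && length(cpc_allowlist) == 0) {
    stop("at least one of uspc_allowlist / cpc_allowlist must be non-empty")
  }
  structure(
    list(date_start = date_start, date_end = date_end,
         uspc_allowlist = as.character(uspc_allowlist),
         cpc_allowlist = as.character(cpc_allowlist),
         match_mode = match_mode),
    class = "filter_criteria"
  )
}

#' Illustrative default classification allowlist
#'
#' A small set of CPC/USPC patterns in the medical and pharmaceutical
#' classification ranges (A61 "medical or veterinary science", C12
#' biochemistry subclasses, USPC 424/514 drug classes). The real study-scale
#' code list is configuration data supplied by the analyst, not part of the
#' method; this default exists so examples and tests run out of the box.
#'
#' @return A `filter_criteria`-ready list with `uspc` and `cpc` components.
#' @export
default_code_allowlist <- function() {
  list(
    uspc = c("424", "514", "600", "606", "623"),
    cpc = c("A61B", "A61F", "A61K", "A61M", "A61N", "A61P", "C12N", "C12Q",
            "G01N33")
  )
}

.code_matches <- function(codes, patterns, match_mode) {
  if (length(codes) == 0 || length(patterns) == 0) return(FALSE)
  if (match_mode == "exact") {
    any(codes %in% patterns)
  } else {
    any(vapply(codes, function(code)
      any(startsWith(code, patterns)), logical(1)))
  }
}

#' Test documents against the biomedical inclusion criteria
#'
#' @param corpus A `patent_corpus` tibble (one or more rows).
#' @param criteria A [filter_criteria()] object.
#' @return Logical vector, one element per document. Documents with an
#'   unparseable (`NA`) grant date are rejected with a warning.
#' @export
is_biomedical <- function(corpus, criteria) {
  stopifnot(inherits(criteria, "filter_criteria"))
  dates <- corpus$grant_date
  bad <- is.na(dates)
  if (any(bad)) {
    warning(sum(bad), " document(s) with unparseable grant_date rejected: ",
            paste(utils::head(corpus$doc_id[bad], 5), collapse = ", "))
  }
  in_window <- !bad & dates >= criteria$date_start & dates <= criteria$date_end
  patterns <- c(criteria$uspc_allowlist, criteria$cpc_allowlist)
  code_ok <- vapply(seq_len(nrow(corpus)), function(i) {
    .code_matches(c(corpus$uspc[[i]], corpus$cpc[[i]]), patterns,
                  criteria$match_mode)
  }, logical(1))
  in_window & code_ok
}

#' Filter a corpus to biomedicine
#'
#' Applies [is_biomedical()] and returns the passing documents (in input
#' order) together with an audit report: total counts, counts passing the
#' date and code criteria separately, and per-year totals.
#'
#' @param corpus A `patent_corpus` tibble.
#' @param criteria A [filter_criteria()] object.
#' @return A list with elements `corpus` (the filtered `patent_corpus`) and
#'   `report` (class `filter_report`: `n_total`, `n_pass_date`,
#'   `n_pass_code`, `n_biomedical`, and `per_year`, a tibble with columns
#'   `year`, `total`, `biomedical`, `fraction`).
#' @export
filter_corpus <- function(corpus, criteria) {
  dates <- corpus$grant_date
  pass_date <- !is.na(dates) & dates >= criteria$date_start &
    dates <= criteria$date_end
  patterns <- c(criteria$uspc_allowlist, criteria$cpc_allowlist)
  pass_code <- vapply(seq_len(nrow(corpus)), function(i) {
    .code_matches(c(corpus$uspc[[i]], corpus$cpc[[i]]), patterns,
                  criteria$match_mode)
  }, logical(1))
  keep <- pass_date & pass_code

  year <- as.integer(format(dates, "%Y"))
  per_year <- tibble::tibble(year = year, biomedical = keep) |>
    dplyr::filter(!is.na(.data$year)) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(total = dplyr::n(),
                     biomedical = sum(.data$biomedical),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$biomedical / .data$total) |>
    dplyr::arrange(.data$year)

  report <- structure(
    list(n_total = nrow(corpus),
         n_pass_date = sum(pass_date),
         n_pass_code = sum(pass_code),
         n_biomedical = sum(keep),
         per_year = per_year),
    class = "filter_report"
  )
  out <- corpus[keep, , drop = FALSE]
  class(out) <- unique(c("patent_corpus", class(out)))
  list(corpus = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Patent filter report\n")
  cat(sprintf("  documents read:        %d\n", x$n_total))
  cat(sprintf("  pass date window:      %d\n", x$n_pass_date))
  cat(sprintf("  pass classification:   %d\n", x$n_pass_code))
  cat(sprintf("  biomedical (both):     %d (%.1f%%)\n", x$n_biomedical,
              100 * x$n_biomedical / max(x$n_total, 1)))
  invisible(x)
}

#' Export per-year filter counts as CSV
#'
#' @param report A `filter_report` from [filter_corpus()].
#' @param path Output CSV path (columns year, total, biomedical, fraction).
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.csv(report$per_year, path, row.names = FALSE)
  invisible(path)
}
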