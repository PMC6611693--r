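#' Disease lexicon
#'
#' A lexicon maps surface terms (possibly multiword) to UMLS-style Concept
#' Unique Identifiers (CUIs). Matching is case-insensitive on token
#' boundaries; each surface term maps to exactly one CUI.
#'
#' @param term Character vector of non-empty surface terms.
#' @param cui Character vector of CUIs, same length.
#' @return A tibble of class `lexicon` with columns `term`, `cui` and a
#'   `tokens` list column holding the lowercase token split of each term.
#' @export
lexicon <- function(term, cui) {
  stopifnot(length(term) == length(cui), length(term) > 0)
  if (any(!nzchar(term))) stop("lexicon terms must be non-empty")
  toks <- tokenize(as.character(term), lowercase = TRUE)
  if (length(term) == 1L) toks <- list(toks)
  key <- vapply(toks, paste, character(1), collapse = " ")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("surface terms map to more than one CUI after token normalization: ",
         paste(utils::head(dup, 3), collapse = "; "))
  }
  out <- tibble::tibble(term = as.character(term), cui = as.character(cui),
                        tokens = toks)
  class(out) <- c("lexicon", class(out))
  out
}

#' Read a lexicon file
#'
#' Tab-separated, two columns (`term`, `cui`), UTF-8, `#` comment lines.
#'
#' @param path File path.
#' @return A `lexicon` tibble.
#' @export
read_lexicon <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  lexicon(tab$term, tab$cui)
}

#' Write a lexicon file
#' @param lex A `lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  utils::write.table(lex[, c("term", "cui")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Concept-to-PheCode mapping bundle
#'
#' Holds the mapping tables used to roll a recognized CUI up to root
#' PheCodes: CUI to ICD-9-CM, ICD-9-CM to PheCode, and PheCode to root
#' PheCode (roots map to themselves), plus an optional ICD-10-CM to
#' ICD-9-CM bridge for claims-derived tables. One-to-many relations are
#' encoded as multiple rows of the two-column tables.
#'
#' @param cui_to_icd9 Data frame with columns `source` (CUI), `target`
#'   (ICD-9-CM code).
#' @param icd9_to_phecode Data frame `source` (ICD-9-CM), `target` (PheCode).
#' @param phecode_to_root Data frame `source` (PheCode), `target` (root
#'   PheCode); each PheCode must have exactly one root, roots map to
#'   themselves.
#' @param icd10_to_icd9 Optional data frame `source` (ICD-10-CM), `target`
#'   (ICD-9-CM).
#' @return A list of class `mapping_bundle`.
#' @export
mapping_bundle <- function(cui_to_icd9, icd9_to_phecode, phecode_to_root,
                           icd10_to_icd9 = NULL) {
  as_map <- function(x, nm) {
    x <- tibble::as_tibble(x)
    names(x)[1:2] <- c("source", "target")
    x$source <- as.character(x$source)
    x$target <- as.character(x$target)
    if (any(!nzchar(x$source)) || any(!nzchar(x$target))) {
      stop("empty keys in mapping table ", nm)
    }
    dplyr::distinct(x)
  }
  cui_to_icd9 <- as_map(cui_to_icd9, "cui_to_icd9")
  icd9_to_phecode <- as_map(icd9_to_phecode, "icd9_to_phecode")
  phecode_to_root <- as_map(phecode_to_root, "phecode_to_root")
  if (anyDuplicated(phecode_to_root$source)) {
    stop("phecode_to_root must map each PheCode to exactly one root")
  }
  dangling <- setdiff(icd9_to_phecode$target, phecode_to_root$source)
  if (length(dangling) > 0) {
    stop("PheCode(s) without a root in phecode_to_root: ",
         paste(utils::head(dangling, 5), collapse = ", "))
  }
  roots <- unique(phecode_to_root$target)
  self <- phecode_to_root$target[match(roots, phecode_to_root$source)]
  if (any(is.na(self)) || any(self != roots)) {
    stop("root PheCodes must map to themselves in phecode_to_root")
  }
  if (!is.null(icd10_to_icd9)) icd10_to_icd9 <- as_map(icd10_to_icd9, "icd10")
  structure(
    list(cui_to_icd9 = cui_to_icd9, icd9_to_phecode = icd9_to_phecode,
         phecode_to_root = phecode_to_root, icd10_to_icd9 = icd10_to_icd9),
    class = "mapping_bundle"
  )
}

#' Read a two-column mapping table
#'
#' Tab-separated `source`/`target` pairs, `#` comments; one row per pair,
#' multiple rows encode one-to-many relations.
#'
#' @param path File path.
#' @return Tibble with columns `source`, `target`.
#' @export
read_mapping_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                           colClasses = "character")
  names(tab)[1:2] <- c("source", "target")
  tibble::as_tibble(tab)
}

#' Write a two-column mapping table
#' @param map Tibble with columns `source`, `target`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(map, path) {
  utils::write.table(map, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Internal: index lexicon entries by their first token for fast longest-match.
.lexicon_index <- function(lex) {
  first <- vapply(lex$tokens, `[`, character(1), 1)
  split(seq_len(nrow(lex)), first)
}

#' Recognize disease concepts in a document
#'
#' Dictionary recognizer: greedy longest-match, left-to-right,
#' case-insensitive, on token boundaries, over the title, abstract and
#' claims sections. Shorter matches overlapping an accepted longer match are
#' suppressed; the scan resumes after the accepted match, so mentions never
#' overlap in token space. Deterministic.
#'
#' @param doc One-row `patent_corpus` tibble (or any row with `doc_id`,
#'   `title`, `abstract`, `claims`).
#' @param lex A [lexicon()].
#' @return Tibble with columns `doc_id`, `section`, `surface` (the original
#'   token slice), `cui`, `start`, `end` (0-based half-open token indices).
#' @export
recognize <- function(doc, lex) {
  stopifnot(nrow(lex) > 0)
  idx <- .lexicon_index(lex)
  out <- list()
  for (section in c("title", "abstract", "claims")) {
    toks_orig <- tokenize(doc[[section]][[1]])
    if (length(toks_orig) == 0) next
    toks <- tolower(toks_orig)
    i <- 1L
    n <- length(toks)
    while (i <= n) {
      cands <- idx[[toks[[i]]]]
      best_len <- 0L
      best_row <- NA_integer_
      if (!is.null(cands)) {
        for (r in cands) {
          tt <- lex$tokens[[r]]
          len <- length(tt)
          if (len > best_len && i + len - 1L <= n &&
              identical(toks[i:(i + len - 1L)], tt)) {
            best_len <- len
            best_row <- r
          }
        }
      }
      if (best_len > 0L) {
        out[[length(out) + 1L]] <- list(
          doc_id = doc$doc_id[[1]], section = section,
          surface = paste(toks_orig[i:(i + best_len - 1L)], collapse = " "),
          cui = lex$cui[[best_row]],
          start = i - 1L, end = i - 1L + best_len
        )
        i <- i + best_len
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(doc_id = character(0), section = character(0),
                          surface = character(0), cui = character(0),
                          start = integer(0), end = integer(0)))
  }
  dplyr::bind_rows(lapply(out, tibble::as_tibble))
}

#' Roll a CUI up to root PheCodes
#'
#' Composes CUI -> ICD-9-CM set -> PheCode set -> root PheCode set. A
#' mapping is *definitive* when the final root set has exactly one element
#' (one-to-one or many-to-one); one-to-many rollups are ambiguous. CUIs
#' absent from the CUI table return an empty set with `definitive = FALSE`.
#' Output is invariant to row order of the mapping tables.
#'
#' @param cui A single CUI string.
#' @param bundle A [mapping_bundle()].
#' @return List with `roots` (sorted character vector of root PheCodes) and
#'   `definitive` (logical).
#' @export
rollup <- function(cui, bundle) {
  stopifnot(inherits(bundle, "mapping_bundle"))
  icd9 <- bundle$cui_to_icd9$target[bundle$cui_to_icd9$source == cui]
  if (length(icd9) == 0) return(list(roots = character(0), definitive = FALSE))
  phe <- unique(bundle$icd9_to_phecode$target[
    bundle$icd9_to_phecode$source %in% icd9])
  if (length(phe) == 0) return(list(roots = character(0), definitive = FALSE))
  pos <- match(phe, bundle$phecode_to_root$source)
  if (anyNA(pos)) {
    stop("PheCode without a root encountered for CUI ", cui,
         " (mapping bundle invariant violated)")
  }
  roots <- sort(unique(bundle$phecode_to_root$target[pos]))
  list(roots = roots, definitive = length(roots) == 1L)
}

#' Annotate a corpus with root PheCodes
#'
#' Runs [recognize()] on every document and rolls each mention's CUI up to
#' root PheCodes via [rollup()]. Per document the root sets are unioned.
#' Under `ambiguity_policy = "all"` an ambiguous rollup contributes every
#' candidate root; under `"drop"` it contributes none. Documents with no
#' disease mention get an empty root set.
#'
#' @param corpus A `patent_corpus` tibble.
#' @param lex A [lexicon()].
#' @param bundle A [mapping_bundle()].
#' @param ambiguity_policy `"all"` (default; the ambiguous-mapping error is
#'   bounded and small) or `"drop"` (sensitivity analysis).
#' @return Tibble with columns `doc_id` and `roots` (list of sorted root
#'   PheCode character vectors).
#' @export
annotate_corpus <- function(corpus, lex, bundle,
                            ambiguity_policy = c("all", "drop")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  cache <- new.env(parent = emptyenv())
  roots_for <- function(cui) {
    if (!is.null(cache[[cui]])) return(cache[[cui]])
    r <- rollup(cui, bundle)
    val <- if (r$definitive || ambiguity_policy == "all") r$roots
           else character(0)
    cache[[cui]] <- val
    val
  }
  roots <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    mention <- recognize(corpus[i, ], lex)
    if (nrow(mention) == 0) {
      roots[[i]] <- character(0)
    } else {
      roots[[i]] <- sort(unique(unlist(lapply(unique(mention$cui), roots_for))))
    }
  }
  tibble::tibble(doc_id = corpus$doc_id, roots = roots)
}

#' Write annotations as long TSV
#'
#' One `doc_id`/`root_phecode` row per pair; documents with empty root sets
#' are written with an empty `root_phecode` so the document set round-trips.
#'
#' @param annotations Tibble from [annotate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  long <- tidyr::unnest(
    dplyr::mutate(annotations, roots = lapply(.data$roots, function(r)
      if (length(r) == 0) "" else r)),
    "roots"
  )
  names(long) <- c("doc_id", "root_phecode")
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#' @param path TSV path.
#' @return Tibble with `doc_id` and `roots` list column.
#' @export
read_annotations <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character", fileEncoding = "UTF-8")
  split_roots <- split(long$root_phecode, long$doc_id)
  ids <- unique(long$doc_id)
  tibble::tibble(
    doc_id = ids,
    roots = lapply(ids, function(id) {
      r <- split_roots[[id]]
      sort(unique(r[nzchar(r)]))
    })
  )
}

#' Audit the definitiveness of CUI-to-root-PheCode mappings
#'
#' For a set of CUIs, classifies each as definitive (rollup yields exactly
#' one root PheCode), ambiguous (more than one root), or unmapped (no
#' rollup). Percentages are over mapped CUIs only; unmapped CUIs are counted
#' separately. Definitive and ambiguous percentages sum to 100 over mapped
#' CUIs.
#'
#' @param bundle A [mapping_bundle()].
#' @param cuis Non-empty character vector of CUIs.
#' @return List of class `mapping_audit`: `n_cuis`, `n_mapped`, `n_unmapped`,
#'   `n_definitive`, `n_ambiguous`, `definitive_pct`, `ambiguous_pct` (both
#'   `NA` when no CUI maps).
#' @export
mapping_audit <- function(bundle, cuis) {
  if (length(cuis) == 0) stop("mapping_audit requires a non-empty CUI set")
  cuis <- unique(cuis)
  # vectorized rollup: join the three tables, then count distinct roots per
  # CUI (equivalent to per-CUI rollup(); scales to large audits)
  chain <- bundle$cui_to_icd9[bundle$cui_to_icd9$source %in% cuis, ]
  names(chain) <- c("cui", "icd9")
  chain <- dplyr::inner_join(chain, bundle$icd9_to_phecode,
                             by = c(icd9 = "source"))
  names(chain)[names(chain) == "target"] <- "phecode"
  chain <- dplyr::inner_join(chain, bundle$phecode_to_root,
                             by = c(phecode = "source"))
  per_cui <- chain |>
    dplyr::distinct(.data$cui, root = .data$target) |>
    dplyr::count(.data$cui, name = "n_roots")
  n_def <- sum(per_cui$n_roots == 1L)
  n_amb <- sum(per_cui$n_roots > 1L)
  n_mapped <- n_def + n_amb
  n_unmapped <- length(cuis) - n_mapped
  structure(
    list(n_cuis = length(cuis), n_mapped = n_mapped, n_unmapped = n_unmapped,
         n_definitive = n_def, n_ambiguous = n_amb,
         definitive_pct = if (n_mapped > 0) 100 * n_def / n_mapped else NA_real_,
         ambiguous_pct = if (n_mapped > 0) 100 * n_amb / n_mapped else NA_real_),
    class = "mapping_audit"
  )
}

#' @export
print.mapping_audit <- function(x, ...) {
  cat("CUI -> root PheCode mapping audit\n")
  cat(sprintf("  CUIs audited:  %d (mapped %d, unmapped %d)\n",
              x$n_cuis, x$n_mapped, x$n_unmapped))
  if (is.na(x$definitive_pct)) {
    cat("  definitive %:  undefined (no mapped CUIs)\n")
  } else {
    cat(sprintf("  definitive %%:  %.1f   ambiguous %%: %.1f\n",
                x$definitive_pct, x$ambiguous_pct))
  }
  invisible(x)
}

#' Bridge ICD-10-CM codes to ICD-9-CM
#'
#' Optional extra table hop for claims-derived burden tables coded in
#' ICD-10-CM after the 2015 coding switch: maps each ICD-10-CM code to its
#' ICD-9-CM equivalents so the usual ICD-9 rollup applies.
#'
#' @param icd10_codes Character vector.
#' @param bundle A [mapping_bundle()] with a non-NULL `icd10_to_icd9` table.
#' @return List of character vectors of ICD-9-CM codes (empty when unmapped).
#' @export
bridge_icd10 <- function(icd10_codes, bundle) {
  if (is.null(bundle$icd10_to_icd9)) {
    stop("mapping bundle has no icd10_to_icd9 table")
  }
  lapply(icd10_codes, function(code) {
    sort(unique(bundle$icd10_to_icd9$target[
      bundle$icd10_to_icd9$source == code]))
  })
}
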