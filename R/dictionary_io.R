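# Core dictionary types and TSV/JSONL input-output shared by all stages.

#' Semantic categories handled by the pipeline
#'
#' Every term, classifier, and evaluation is bound to exactly one of the
#' three clinical categories used throughout: medical problems,
#' medications, and medical tests.
#' @export
CATEGORIES <- c("PROBLEM", "MEDICATION", "TEST")

#' @noRd
check_category <- function(category) {
  if (length(category) != 1L || !category %in% CATEGORIES) {
    stop("unknown category: ", paste(category, collapse = ", "),
         " (expected one of ", paste(CATEGORIES, collapse = ", "), ")",
         call. = FALSE)
  }
  category
}

#' @noRd
check_language <- function(language) {
  match.arg(language, c("en", "zh"))
}

#' Normalize a raw term surface
#'
#' Applies Unicode NFC normalization, collapses runs of whitespace to a
#' single space, trims, and lowercases English (Chinese is kept verbatim:
#' case does not exist and characters are matched exactly). This is the
#' canonical matching form used on both sides of every seed/candidate
#' comparison.
#'
#' @param raw character vector of raw surfaces.
#' @param language `"en"` or `"zh"`.
#' @return character vector of normalized surfaces; empty strings where
#'   nothing remains.
#' @examples
#' normalize_term("  Chest   X-Ray ", "en")
#' @export
normalize_term <- function(raw, language = c("en", "zh")) {
  language <- check_language(language)
  if (length(raw) == 0L) return(character(0))
  x <- stringi::stri_trans_nfc(as.character(raw))
  x[is.na(x)] <- ""
  x <- gsub("[\\s 　]+", " ", x, perl = TRUE)
  x <- trimws(x)
  if (language == "en") x <- stringi::stri_trans_tolower(x)
  x
}

#' Construct a seed dictionary
#'
#' A seed dictionary maps each category to a deduplicated set of
#' normalized surfaces. A surface may legitimately belong to more than
#' one category; duplicates within a category are removed.
#'
#' @param language `"en"` or `"zh"`.
#' @param entries named list mapping category labels to character vectors.
#' @return an object of class `seed_dictionary`.
#' @export
seed_dictionary <- function(language = c("en", "zh"), entries = list()) {
  language <- check_language(language)
  out <- stats::setNames(vector("list", length(CATEGORIES)), CATEGORIES)
  for (cat in CATEGORIES) out[[cat]] <- character(0)
  for (cat in names(entries)) {
    check_category(cat)
    surf <- normalize_term(entries[[cat]], language)
    surf <- surf[nzchar(surf)]
    out[[cat]] <- sort(unique(surf), method = "radix")
  }
  structure(list(language = language, entries = out),
            class = "seed_dictionary")
}

#' @export
print.seed_dictionary <- function(x, ...) {
  cat("<seed_dictionary> language:", x$language, "\n")
  for (cat in CATEGORIES) {
    cat("  ", format(cat, width = 10), length(x$entries[[cat]]), "terms\n")
  }
  invisible(x)
}

#' Number of entries per category
#' @param d a `seed_dictionary`.
#' @return named integer vector over categories.
#' @export
dictionary_sizes <- function(d) {
  vapply(d$entries, length, integer(1))
}

#' Load a seed dictionary from TSV
#'
#' The file format is `term<TAB>category`, UTF-8, no quoting, one term per
#' line, with category in `PROBLEM`, `MEDICATION`, `TEST`. Rows are
#' normalized and deduplicated per category. Malformed rows (wrong column
#' count, unknown category) abort with the offending line number; terms
#' containing tabs or newlines cannot survive this dialect by
#' construction.
#'
#' @param path path to a TSV file.
#' @param language `"en"` or `"zh"`.
#' @return a `seed_dictionary`.
#' @export
load_dictionary <- function(path, language = c("en", "zh")) {
  language <- check_language(language)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warning("empty dictionary file: ", path, call. = FALSE)
    return(seed_dictionary(language))
  }
  entries <- stats::setNames(
    replicate(length(CATEGORIES), character(0), simplify = FALSE), CATEGORIES)
  for (i in which(keep)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L) {
      stop("malformed dictionary row at line ", i, " of ", path,
           ": expected 2 tab-separated columns, got ", length(fields),
           call. = FALSE)
    }
    if (!fields[[2]] %in% CATEGORIES) {
      stop("unknown category '", fields[[2]], "' at line ", i, " of ", path,
           call. = FALSE)
    }
    entries[[fields[[2]]]] <- c(entries[[fields[[2]]]], fields[[1]])
  }
  seed_dictionary(language, entries)
}

#' Save a seed dictionary to TSV
#'
#' Inverse of [load_dictionary()]: `load_dictionary(save_dictionary(d))`
#' reproduces `d` exactly for normalized dictionaries. When `provenance`
#' (a candidate pool or list thereof) is supplied, a JSONL sidecar
#' `<path>.provenance.jsonl` records the source lists of each term.
#'
#' @param d a `seed_dictionary`.
#' @param path output path.
#' @param provenance optional `candidate_pool` (or list of pools) whose
#'   source records should be written alongside.
#' @return `path`, invisibly.
#' @export
save_dictionary <- function(d, path, provenance = NULL) {
  stopifnot(inherits(d, "seed_dictionary"))
  rows <- character(0)
  for (cat in CATEGORIES) {
    if (length(d$entries[[cat]])) {
      rows <- c(rows, paste(d$entries[[cat]], cat, sep = "\t"))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(rows, con, useBytes = TRUE)
  if (!is.null(provenance)) {
    pools <- if (inherits(provenance, "candidate_pool")) list(provenance) else provenance
    recs <- list()
    for (pool in pools) {
      for (surf in names(pool$terms)) {
        recs[[length(recs) + 1L]] <- list(
          term = surf, category = pool$category,
          sources = pool$terms[[surf]]$sources)
      }
    }
    write_jsonl(recs, paste0(path, ".provenance.jsonl"))
  }
  invisible(path)
}

#' Merge two seed dictionaries
#'
#' Per-category set union; commutative, associative, and idempotent, with
#' the empty dictionary as identity. Both dictionaries must share a
#' language.
#'
#' @param a,b `seed_dictionary` objects.
#' @return the merged `seed_dictionary`.
#' @export
merge_dictionaries <- function(a, b) {
  stopifnot(inherits(a, "seed_dictionary"), inherits(b, "seed_dictionary"))
  if (a$language != b$language) {
    stop("cannot merge dictionaries of different languages", call. = FALSE)
  }
  entries <- lapply(stats::setNames(CATEGORIES, CATEGORIES), function(cat) {
    union(a$entries[[cat]], b$entries[[cat]])
  })
  seed_dictionary(a$language, entries)
}
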