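# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, then restores the caller's RNG state so
#' library functions never perturb user-level randomness.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' Keeps every stochastic stage (pair sampling, negative sampling,
#' precision sampling, ...) on an independent but deterministic stream.
#' Result is always a valid 32-bit integer seed.
#' @noRd
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647L)
}

#' @noRd
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

#' @noRd
write_jsonl <- function(records, path) {
  txt <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Length of a term in the unit the pipeline scores
#'
#' English terms are measured in whitespace-separated words, Chinese terms
#' in characters (spaces excluded), matching how list and entity lengths
#' are assessed throughout.
#' @param x character vector of normalized terms.
#' @param language `"en"` or `"zh"`.
#' @return integer vector of lengths.
#' @export
term_length <- function(x, language = c("en", "zh")) {
  language <- match.arg(language)
  if (language == "en") {
    vapply(strsplit(trimws(x), "\\s+"), function(t) length(t[nzchar(t)]),
           integer(1))
  } else {
    nchar(gsub(" ", "", x, fixed = TRUE))
  }
}

#' @noRd
html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
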