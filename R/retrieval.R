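# Offline page/snippet stores and query-pair generation.
#
# Live search engines sit behind these two store contracts; the shipped
# implementations are directory-backed (JSONL manifests), so the core
# pipeline contains no network code.

#' Generate two-term queries from a seed dictionary
#'
#' Queries pairing two seed terms of the same category are what surface
#' pages with parallel structures: a page matching both terms very likely
#' enumerates entities of that category. Pairs are unordered (canonical
#' lexicographic order), drawn uniformly without replacement from the
#' `choose(n, 2)` possibilities, and deterministic under `rng_seed`.
#'
#' @param seeds a [seed_dictionary()].
#' @param category one of `CATEGORIES`.
#' @param max_pairs maximum number of pairs to return.
#' @param rng_seed integer seed for the draw.
#' @return data.frame with columns `term_a`, `term_b`, `category`;
#'   `min(max_pairs, choose(n, 2))` rows.
#' @export
generate_query_pairs <- function(seeds, category, max_pairs = 100L,
                                 rng_seed = 1L) {
  check_category(category)
  stopifnot(max_pairs >= 1L)
  terms <- sort(seeds$entries[[category]], method = "radix")
  n <- length(terms)
  if (n < 2L) {
    stop("category ", category, " has fewer than 2 seed terms; ",
         "cannot form query pairs", call. = FALSE)
  }
  total <- n * (n - 1) / 2
  m <- min(max_pairs, total)
  idx <- with_seed(rng_seed, sample(total, m))
  # Map a pair index (lexicographic over i < j) back to (i, j) without
  # materializing all choose(n, 2) pairs.
  cum <- c(0, cumsum(n - seq_len(n - 1L)))
  i <- findInterval(idx - 0.5, cum)
  j <- i + (idx - cum[i])
  data.frame(term_a = terms[i], term_b = terms[j],
             category = category, stringsAsFactors = FALSE)
}

#' @noRd
pair_key <- function(a, b) {
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  paste(lo, hi, sep = "\r")
}

#' Open a directory-backed page store
#'
#' The manifest is JSONL with records
#' `{"page_id": str, "path": str, "query": [termA, termB]}`; `path` is
#' resolved relative to the manifest's directory.
#'
#' @param manifest_path path to the manifest JSONL.
#' @return an object of class `page_store`.
#' @export
page_store <- function(manifest_path) {
  recs <- read_jsonl(manifest_path)
  man <- data.frame(
    page_id = vapply(recs, function(r) as.character(r$page_id), character(1)),
    path = vapply(recs, function(r) as.character(r$path), character(1)),
    term_a = vapply(recs, function(r) as.character(r$query[[1]]), character(1)),
    term_b = vapply(recs, function(r) as.character(r$query[[2]]), character(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(man$page_id)) {
    stop("duplicate page_id in manifest ", manifest_path, call. = FALSE)
  }
  structure(list(manifest = man, root = dirname(manifest_path)),
            class = "page_store")
}

#' @export
print.page_store <- function(x, ...) {
  cat("<page_store>", nrow(x$manifest), "pages under", x$root, "\n")
  invisible(x)
}

#' Fetch the pages issued for a set of query pairs
#'
#' Returns every manifest page whose issuing query matches one of `pairs`
#' under canonical (unordered) comparison, deduplicated by `page_id`.
#' Pages whose HTML file is missing are skipped with a warning; the number
#' of skips is attached as attribute `skipped`.
#'
#' @param store a [page_store()].
#' @param pairs data.frame as returned by [generate_query_pairs()].
#' @return list of `list(page_id =, html =)` records.
#' @export
fetch_pages <- function(store, pairs) {
  stopifnot(inherits(store, "page_store"))
  if (NROW(pairs) == 0L) {
    return(structure(list(), skipped = 0L))
  }
  wanted <- unique(pair_key(pairs$term_a, pairs$term_b))
  man <- store$manifest
  hit <- pair_key(man$term_a, man$term_b) %in% wanted
  man <- man[hit & !duplicated(man$page_id), , drop = FALSE]
  out <- list()
  skipped <- 0L
  for (r in seq_len(nrow(man))) {
    fp <- file.path(store$root, man$path[[r]])
    if (!file.exists(fp)) {
      warning("missing html file for page ", man$page_id[[r]], ": ", fp,
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    html <- paste(readLines(fp, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
    out[[length(out) + 1L]] <- list(page_id = man$page_id[[r]], html = html)
  }
  structure(out, skipped = skipped)
}

#' Open a snippet store
#'
#' Snippets are search-result records for a query term: title, URL, and a
#' short context in which the term occurs. The store is JSONL with records
#' `{"term": str, "rank": int, "title": str, "url": str, "context": str}`.
#'
#' @param path path to the snippet JSONL file.
#' @return an object of class `snippet_store`.
#' @export
snippet_store <- function(path) {
  recs <- read_jsonl(path)
  df <- data.frame(
    term = vapply(recs, function(r) as.character(r$term), character(1)),
    rank = vapply(recs, function(r) as.integer(r$rank), integer(1)),
    title = vapply(recs, function(r) as.character(r$title %||% ""), character(1)),
    url = vapply(recs, function(r) as.character(r$url %||% ""), character(1)),
    context = vapply(recs, function(r) as.character(r$context), character(1)),
    stringsAsFactors = FALSE)
  structure(list(snippets = df, index = split(seq_len(nrow(df)), df$term)),
            class = "snippet_store")
}

#' @export
print.snippet_store <- function(x, ...) {
  cat("<snippet_store>", nrow(x$snippets), "snippets for",
      length(x$index), "terms\n")
  invisible(x)
}

#' Fetch the stored snippets for one term
#'
#' At most the top 100 snippets are returned, in rank order; an unknown
#' term yields an empty set, which models rare terms with no web
#' presence.
#'
#' @param store a [snippet_store()].
#' @param term query term (normalized surface).
#' @param max_snippets cap on returned snippets (default 100).
#' @return data.frame of snippet records, possibly empty.
#' @export
fetch_snippets <- function(store, term, max_snippets = 100L) {
  stopifnot(inherits(store, "snippet_store"))
  rows <- store$index[[term]]
  if (is.null(rows)) {
    return(store$snippets[0, , drop = FALSE])
  }
  df <- store$snippets[rows, , drop = FALSE]
  df <- df[order(df$rank), , drop = FALSE]
  utils::head(df, max_snippets)
}
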