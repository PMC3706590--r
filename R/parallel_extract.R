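# Parallel-structure mining: group DOM text nodes by tag-class path into
# candidate lists, select lists rich in seed terms, clean them, and
# aggregate candidates with provenance.

#' Default punctuation set used by list cleanup
#'
#' ASCII and full-width sentence punctuation plus brackets and quotes.
#' Hyphen and percent are deliberately excluded: they are common inside
#' legitimate English medical terms ("x-ray", "50% dextrose").
#' @return character vector of single characters.
#' @export
default_punct_set <- function() {
  strsplit("，。；：！？、,.;:!?()（）[]【】“”\"<>", "")[[1]]
}

#' @noRd
new_candidate_list <- function(list_id, page_id, path, items, language,
                               hits = character(0)) {
  structure(list(
    list_id = list_id, page_id = page_id, path = path,
    items = items, hits = hits,
    H_L = length(hits), N_L = length(items),
    mean_len = mean(term_length(items, language)),
    language = language), class = "candidate_list")
}

#' @export
print.candidate_list <- function(x, ...) {
  cat("<candidate_list>", x$list_id, "on", x$page_id, "\n  path:", x$path,
      "\n  N_L:", x$N_L, " H_L:", x$H_L,
      " mean_len:", round(x$mean_len, 2), "\n")
  invisible(x)
}

#' @noRd
canonical_class <- function(cls) {
  if (is.na(cls)) return("empty")
  toks <- strsplit(trimws(cls), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return("empty")
  paste(sort(toks, method = "radix"), collapse = "+")
}

#' Group the text nodes of a page into candidate lists by tag-class path
#'
#' The tag-class path of a text node is the sequence of (tag, class)
#' pairs from the document root down to its parent element; tags without
#' a class attribute get class `"empty"`, and multi-valued class
#' attributes are canonicalized as the sorted token set joined by `"+"`.
#' Nodes sharing a path occupy analogous positions in a parallel
#' structure (same column of a table, same role in a list) and typically
#' share typography, so their texts are collected into one candidate
#' list. A "text node" is a maximal text run directly under one element;
#' text is never concatenated across child elements.
#'
#' Script/style content, comments, and whitespace-only nodes are
#' excluded. Items are normalized with [normalize_term()]. Only groups
#' with at least `min_items` members qualify: a singleton carries no
#' parallel structure. Unparseable input yields an empty result with a
#' warning rather than an error.
#'
#' @param html_text raw HTML as a single string (tag soup tolerated).
#' @param page_id identifier recorded on each produced list.
#' @param language `"en"` or `"zh"`.
#' @param min_items minimum group size to qualify as a list (default 2).
#' @return list of `candidate_list` objects.
#' @export
extract_candidate_lists <- function(html_text, page_id,
                                    language = c("en", "zh"),
                                    min_items = 2L) {
  language <- check_language(language)
  doc <- tryCatch(xml2::read_html(html_text),
                  error = function(e) NULL)
  if (is.null(doc)) {
    warning("unparseable document for page ", page_id, call. = FALSE)
    return(list())
  }
  acc <- new.env(parent = emptyenv())
  acc$paths <- character(0)
  acc$texts <- character(0)
  walk <- function(node, path) {
    for (child in xml2::xml_contents(node)) {
      type <- xml2::xml_type(child)
      if (type == "element") {
        tag <- tolower(xml2::xml_name(child))
        if (tag %in% c("script", "style")) next
        seg <- paste0(tag, ".", canonical_class(xml2::xml_attr(child, "class")))
        walk(child, paste0(path, if (nzchar(path)) "/" else "", seg))
      } else if (type %in% c("text", "cdata")) {
        txt <- xml2::xml_text(child)
        if (nzchar(trimws(txt))) {
          acc$paths <- c(acc$paths, path)
          acc$texts <- c(acc$texts, txt)
        }
      }
    }
  }
  root <- xml2::xml_root(doc)
  walk(root, paste0(tolower(xml2::xml_name(root)), ".",
                    canonical_class(xml2::xml_attr(root, "class"))))
  if (!length(acc$texts)) return(list())
  items <- normalize_term(acc$texts, language)
  keep <- nzchar(items)
  groups <- split(items[keep], acc$paths[keep])
  groups <- groups[vapply(groups, length, integer(1)) >= min_items]
  if (!length(groups)) return(list())
  groups <- groups[sort(names(groups), method = "radix")]
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    out[[g]] <- new_candidate_list(
      list_id = sprintf("%s-L%03d", page_id, g), page_id = page_id,
      path = names(groups)[[g]], items = unname(groups[[g]]),
      language = language)
  }
  out
}

#' Select candidate lists containing many seed terms
#'
#' A list is retained iff its hit count `H_L` -- the number of distinct
#' seed terms among its (distinct) items -- is strictly greater than `k`.
#' Retained lists carry their hit count and the matched seed surfaces.
#'
#' @param lists list of `candidate_list` objects.
#' @param seeds character vector of normalized seed surfaces.
#' @param k hit-count threshold (default 10; strictly-greater rule).
#' @return the retained lists, hit counts populated.
#' @export
select_lists <- function(lists, seeds, k = 10L) {
  out <- list()
  for (l in lists) {
    hits <- intersect(unique(l$items), seeds)
    if (length(hits) > k) {
      l$hits <- hits
      l$H_L <- length(hits)
      out[[length(out) + 1L]] <- l
    }
  }
  out
}

#' Clean a candidate list
#'
#' Removes items that are too long for an in-domain term (length measured
#' in English words or Chinese characters) or that contain any character
#' of `punct_set`; long or punctuated items are typically sentence
#' fragments, dosage strings, or codes. `N_L`, `mean_len`, and `H_L` are
#' recomputed on the survivors. Idempotent; may return an empty list,
#' which callers discard.
#'
#' @param l a `candidate_list`.
#' @param language `"en"` or `"zh"`; defaults to the list's own.
#' @param max_len maximum item length (default `3 * l_p`: 6 English
#'   words, 15 Chinese characters).
#' @param punct_set characters that disqualify an item
#'   (default [default_punct_set()]).
#' @return the cleaned `candidate_list`.
#' @export
clean_list <- function(l, language = l$language,
                       max_len = if (language == "en") 6L else 15L,
                       punct_set = default_punct_set()) {
  stopifnot(max_len >= 1L)
  language <- check_language(language)
  items <- l$items
  if (length(items)) {
    too_long <- term_length(items, language) > max_len
    has_punct <- vapply(strsplit(items, "", fixed = TRUE),
                        function(ch) any(ch %in% punct_set), logical(1))
    items <- items[!too_long & !has_punct]
  }
  l$items <- items
  l$N_L <- length(items)
  l$mean_len <- if (length(items)) mean(term_length(items, language)) else 0
  l$hits <- intersect(l$hits, unique(items))
  l$H_L <- length(l$hits)
  l
}

#' Aggregate cleaned candidate lists into a candidate pool
#'
#' Pools all items under their normalized surface, keeping for every term
#' the exact set of `(page_id, list_id)` pairs it was seen on. This
#' provenance drives the later form-based scoring (how many lists a term
#' appears on, and how good those lists are).
#'
#' @param lists list of selected, cleaned `candidate_list` objects.
#' @param category one of `CATEGORIES`.
#' @return an object of class `candidate_pool`: `terms` maps surface to
#'   `list(sources = list(c(page_id, list_id), ...))`.
#' @export
aggregate_candidates <- function(lists, category) {
  check_category(category)
  terms <- new.env(parent = emptyenv())
  for (l in lists) {
    for (surf in unique(l$items)) {
      prev <- terms[[surf]]
      src <- list(c(l$page_id, l$list_id))
      if (is.null(prev)) {
        terms[[surf]] <- list(sources = src)
      } else {
        keys <- vapply(prev$sources, paste, character(1), collapse = "\r")
        if (!paste(src[[1]], collapse = "\r") %in% keys) {
          prev$sources <- c(prev$sources, src)
          terms[[surf]] <- prev
        }
      }
    }
  }
  term_list <- as.list(terms)
  term_list <- term_list[sort(names(term_list), method = "radix")]
  structure(list(category = category, terms = term_list),
            class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat("<candidate_pool>", length(x$terms), "candidates for", x$category, "\n")
  invisible(x)
}

#' Serialize candidate lists to JSONL
#' @param lists list of `candidate_list` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidate_lists <- function(lists, path) {
  recs <- lapply(lists, function(l) {
    list(list_id = l$list_id, page_id = l$page_id, path = l$path,
         items = l$items, H_L = l$H_L, N_L = l$N_L, mean_len = l$mean_len)
  })
  write_jsonl(recs, path)
}
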