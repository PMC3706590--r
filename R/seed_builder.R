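# High-precision seed construction from an encyclopedia dump: tag
# seeding, related-entry expansion, tag expansion, and page keyword
# rules. Mirrors how an initial Chinese seed set is bootstrapped from an
# online encyclopedia; English seeds normally arrive as plain TSV
# (load_dictionary) from annotated corpora.

#' Load an encyclopedia dump from JSONL
#'
#' Records: `{"title": str, "content": str, "tags": [...],
#' "related": [...]}`. Titles must be unique within the dump.
#'
#' @param path path to the JSONL dump.
#' @return named list of entries (by title), class `encyclopedia_dump`.
#' @export
load_encyclopedia <- function(path) {
  recs <- read_jsonl(path)
  titles <- vapply(recs, function(r) as.character(r$title), character(1))
  if (anyDuplicated(titles)) {
    stop("duplicate titles in encyclopedia dump ", path, call. = FALSE)
  }
  entries <- lapply(recs, function(r) {
    list(title = as.character(r$title),
         content = as.character(r$content %||% ""),
         tags = as.character(unlist(r$tags, use.names = FALSE)),
         related = as.character(unlist(r$related, use.names = FALSE)))
  })
  structure(stats::setNames(entries, titles), class = "encyclopedia_dump")
}

#' A page rule: keyword gate on entry content
#'
#' An entry is adopted as a seed of a category only if its content
#' contains at least one of the category's required keywords (for
#' example, a drug page is expected to discuss adverse/side effects).
#' This is the precision guard of the seeding stage.
#'
#' @param category one of `CATEGORIES`.
#' @param required_keywords non-empty character vector; content must
#'   contain at least one as a substring.
#' @return object of class `page_rule`.
#' @export
page_rule <- function(category, required_keywords) {
  check_category(category)
  required_keywords <- as.character(required_keywords)
  if (!length(required_keywords) || !all(nzchar(required_keywords))) {
    stop("page rule needs a non-empty keyword set", call. = FALSE)
  }
  structure(list(category = category,
                 required_keywords = required_keywords),
            class = "page_rule")
}

#' Apply a page rule to an encyclopedia entry
#'
#' Accepts iff any required keyword occurs as a substring of the entry's
#' content; the title is deliberately not consulted.
#'
#' @param entry an entry (list with `content`).
#' @param rule a [page_rule()].
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
apply_page_rule <- function(entry, rule) {
  stopifnot(inherits(rule, "page_rule"))
  content <- entry$content %||% ""
  any(vapply(rule$required_keywords,
             function(kw) grepl(kw, content, fixed = TRUE), logical(1)))
}

#' Build a seed dictionary from an encyclopedia dump
#'
#' Iteration 0 adopts every entry carrying one of the category's seed
#' tags. Each further iteration adds (a) the related entries of current
#' members, and (b), when `tag_expand` is on, entries carrying tags that
#' newly appeared on at least `t_min` freshly accepted entries (the
#' co-occurrence floor curbs topic drift). Every adoption -- tag-seeded,
#' related, or tag-expanded -- must pass the category's page rule, since
#' precision is the sole concern at this stage; coverage is the job of
#' the later web-expansion stages. Stops at a fixed point or after
#' `max_iter` iterations. Related titles absent from the dump are skipped
#' and counted.
#'
#' @param dump an `encyclopedia_dump`.
#' @param seed_tags named list mapping categories to character vectors of
#'   seed tags.
#' @param rules list of [page_rule()] objects (at most one per
#'   category; categories without a rule accept unconditionally).
#' @param max_iter maximum expansion iterations (default 5).
#' @param tag_expand enable tag expansion (default `TRUE`).
#' @param t_min minimum newly-accepted entries a tag must appear on
#'   before it is adopted as a seed tag (default 2).
#' @param language language of the dump (default `"zh"`).
#' @return a [seed_dictionary()] of adopted titles; attribute
#'   `skipped_related` counts unresolvable related links.
#' @export
build_seeds <- function(dump, seed_tags, rules = list(), max_iter = 5L,
                        tag_expand = TRUE, t_min = 2L,
                        language = c("zh", "en")) {
  language <- match.arg(language)
  stopifnot(inherits(dump, "encyclopedia_dump"), max_iter >= 1L)
  rule_by_cat <- list()
  for (r in rules) rule_by_cat[[r$category]] <- r
  passes <- function(title, cat) {
    rule <- rule_by_cat[[cat]]
    is.null(rule) || apply_page_rule(dump[[title]], rule)
  }
  titles <- names(dump)
  tags_of <- lapply(dump, `[[`, "tags")
  skipped <- 0L
  accepted <- stats::setNames(
    replicate(length(CATEGORIES), character(0), simplify = FALSE),
    CATEGORIES)
  active_tags <- lapply(stats::setNames(CATEGORIES, CATEGORIES),
                        function(cat) unique(seed_tags[[cat]] %||% character(0)))
  # iteration 0: tag-seeded adoption
  fresh <- lapply(stats::setNames(CATEGORIES, CATEGORIES), function(cat) {
    cand <- titles[vapply(tags_of, function(tg) any(tg %in% active_tags[[cat]]),
                          logical(1))]
    cand[vapply(cand, passes, logical(1), cat = cat)]
  })
  for (cat in CATEGORIES) accepted[[cat]] <- fresh[[cat]]
  for (iter in seq_len(max_iter)) {
    grew <- FALSE
    for (cat in CATEGORIES) {
      if (!length(fresh[[cat]])) {
        fresh[[cat]] <- character(0)
        next
      }
      new_members <- character(0)
      # (a) related-entry expansion
      rel <- unique(unlist(lapply(fresh[[cat]],
                                  function(tt) dump[[tt]]$related),
                           use.names = FALSE))
      unknown <- setdiff(rel, titles)
      skipped <- skipped + length(unknown)
      rel <- setdiff(intersect(rel, titles), accepted[[cat]])
      new_members <- rel[vapply(rel, passes, logical(1), cat = cat)]
      # (b) tag expansion from freshly accepted entries
      if (tag_expand) {
        tag_counts <- table(unlist(tags_of[fresh[[cat]]], use.names = FALSE))
        new_tags <- setdiff(names(tag_counts)[tag_counts >= t_min],
                            active_tags[[cat]])
        if (length(new_tags)) {
          active_tags[[cat]] <- c(active_tags[[cat]], new_tags)
          cand <- titles[vapply(tags_of, function(tg) any(tg %in% new_tags),
                                logical(1))]
          cand <- setdiff(cand, c(accepted[[cat]], new_members))
          new_members <- c(new_members,
                           cand[vapply(cand, passes, logical(1), cat = cat)])
        }
      }
      new_members <- unique(new_members)
      if (length(new_members)) {
        accepted[[cat]] <- c(accepted[[cat]], new_members)
        grew <- TRUE
      }
      fresh[[cat]] <- new_members
    }
    if (!grew) break
  }
  out <- seed_dictionary(language, accepted)
  attr(out, "skipped_related") <- skipped
  out
}
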