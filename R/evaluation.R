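# Dictionary evaluation: precision by sampled review, three recalls
# (surface / object / head) that handle the heavy surface variability of
# clinical terms, their F-measures, and the false-discard error rate Err
# over removed candidates.

#' Load a reference corpus from TSV
#'
#' Format: `surface<TAB>category<TAB>object_id<TAB>head`, UTF-8. Surfaces
#' sharing an `object_id` are surface variants of one object (e.g. an
#' abbreviation and its full form); `head` is the term's head noun (may
#' be empty, in which case a head extractor is used at evaluation time).
#'
#' @param path TSV path.
#' @param language `"en"` or `"zh"` (surfaces are normalized).
#' @return object of class `reference_corpus`: data.frame `surface`,
#'   `category`, `object_id`, `head`.
#' @export
load_reference <- function(path, language = c("en", "zh")) {
  language <- check_language(language)
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          col.names = c("surface", "category", "object_id",
                                        "head"),
                          colClasses = "character", fill = TRUE)
  df$surface <- normalize_term(df$surface, language)
  df$head <- normalize_term(df$head, language)
  bad <- !df$category %in% CATEGORIES
  if (any(bad)) {
    stop("unknown category in reference corpus at row ", which(bad)[1],
         call. = FALSE)
  }
  reference_corpus(df, language)
}

#' Construct a reference corpus object
#' @param df data.frame with `surface`, `category`, `object_id`, and
#'   optionally `head` columns.
#' @param language `"en"` or `"zh"`.
#' @return object of class `reference_corpus`.
#' @export
reference_corpus <- function(df, language = c("en", "zh")) {
  language <- check_language(language)
  stopifnot(all(c("surface", "category", "object_id") %in% names(df)))
  if (is.null(df$head)) df$head <- ""
  if (any(!nzchar(df$object_id))) {
    stop("every reference term needs an object_id", call. = FALSE)
  }
  structure(as.data.frame(df), language = language,
            class = c("reference_corpus", "data.frame"))
}

#' @noRd
ref_subset <- function(ref, category) {
  if (is.null(category)) return(ref)
  ref[ref$category == category, , drop = FALSE]
}

#' @noRd
as_truth_fun <- function(truth_oracle) {
  if (is.function(truth_oracle)) return(truth_oracle)
  truth_set <- as.character(truth_oracle)
  function(x) x %in% truth_set
}

#' Precision by (sampled) review
#'
#' `P = M / N`: `n_sample` entries are drawn uniformly (seeded) from the
#' dictionary and `M` of them are marked valid by the truth oracle --
#' the sampling estimator used when human judges review a random sample
#' of a large collection. If `n_sample` covers the dictionary, a full
#' census is taken instead (noted via a message).
#'
#' @param dictionary character vector of dictionary surfaces.
#' @param truth_oracle `function(surfaces) -> logical`, or a character
#'   vector of true surfaces.
#' @param n_sample sample size N.
#' @param rng_seed seed for the draw.
#' @return list with `P`, `M`, `N`, and the sampled surfaces.
#' @export
precision_estimate <- function(dictionary, truth_oracle, n_sample = 1000L,
                               rng_seed = 1L) {
  dictionary <- unique(dictionary)
  if (!length(dictionary)) stop("empty dictionary", call. = FALSE)
  oracle <- as_truth_fun(truth_oracle)
  if (n_sample >= length(dictionary)) {
    message("sample covers dictionary; taking full census (N = ",
            length(dictionary), ")")
    sample_terms <- dictionary
  } else {
    sample_terms <- with_seed(rng_seed, sample(dictionary, n_sample))
  }
  M <- sum(oracle(sample_terms))
  list(P = M / length(sample_terms), M = M, N = length(sample_terms),
       sample = sample_terms)
}

#' False-discard error over removed candidates
#'
#' `Err = M / N` on a random sample of the candidates a filtering stage
#' removed, where `M` counts the truly valid terms among them -- an
#' estimate of how much the filter over-deletes.
#'
#' @inheritParams precision_estimate
#' @param removed character vector of removed candidate surfaces.
#' @return list with `Err`, `M`, `N`, and the sampled surfaces.
#' @export
err_estimate <- function(removed, truth_oracle, n_sample = 1000L,
                         rng_seed = 1L) {
  removed <- unique(removed)
  if (!length(removed)) stop("no removed candidates to sample", call. = FALSE)
  res <- precision_estimate(removed, truth_oracle, n_sample, rng_seed)
  list(Err = res$P, M = res$M, N = res$N, sample = res$sample)
}

#' Surface recall
#'
#' Fraction of reference surfaces exactly present in the dictionary:
#' recall in the conventional sense, treating every surface variant as a
#' distinct target.
#'
#' @param dictionary character vector of dictionary surfaces
#'   (normalized).
#' @param ref a `reference_corpus`.
#' @param category restrict to one category (default: all).
#' @return list with `R_S`, `TP`, `N_ref`.
#' @export
surface_recall <- function(dictionary, ref, category = NULL) {
  ref <- ref_subset(ref, category)
  if (!nrow(ref)) stop("empty reference corpus", call. = FALSE)
  TP <- sum(ref$surface %in% dictionary)
  list(R_S = TP / nrow(ref), TP = TP, N_ref = nrow(ref))
}

#' Object recall
#'
#' Fraction of reference objects (synonym classes, identified by
#' `object_id`) with at least one surface form in the dictionary. An
#' abbreviation, a truncated form, and the full form of one disease all
#' count as a single object, so a dictionary holding any of them covers
#' it.
#'
#' @inheritParams surface_recall
#' @return list with `R_O`, `TP`, `N_obj`.
#' @export
object_recall <- function(dictionary, ref, category = NULL) {
  ref <- ref_subset(ref, category)
  if (!nrow(ref)) stop("empty reference corpus", call. = FALSE)
  objects <- unique(ref$object_id)
  covered <- unique(ref$object_id[ref$surface %in% dictionary])
  list(R_O = length(covered) / length(objects), TP = length(covered),
       N_obj = length(objects))
}

#' Default head-noun extractor
#'
#' The head noun of a term is the term minus its modifiers (body parts,
#' chronic/acute, ...), such that term IS-A head: the head of "brain
#' lesion" is "lesion". Heuristic: the longest suffix of the term found
#' in `head_lexicon`; failing that, the term with leading
#' modifier-lexicon matches stripped; failing that, the whole term.
#' English suffixes are word suffixes, Chinese suffixes are character
#' suffixes.
#'
#' @param term surface string (normalized).
#' @param language `"en"` or `"zh"`.
#' @param modifier_lexicon character vector of known modifiers.
#' @param head_lexicon character vector of known head nouns.
#' @return the head string (never empty for non-empty input).
#' @export
default_head_extractor <- function(term, language = c("en", "zh"),
                                   modifier_lexicon = character(0),
                                   head_lexicon = character(0)) {
  language <- check_language(language)
  if (!nzchar(term)) return(term)
  if (language == "en") {
    toks <- strsplit(term, " ", fixed = TRUE)[[1]]
    n <- length(toks)
    for (i in seq_len(n)) {  # longest suffix first
      cand <- paste(toks[i:n], collapse = " ")
      if (cand %in% head_lexicon) return(cand)
    }
    while (length(toks) > 1L && toks[[1]] %in% modifier_lexicon) {
      toks <- toks[-1L]
    }
    paste(toks, collapse = " ")
  } else {
    s <- gsub(" ", "", term, fixed = TRUE)
    n <- nchar(s)
    for (i in seq_len(n)) {
      cand <- substring(s, i, n)
      if (cand %in% head_lexicon) return(cand)
    }
    out <- s
    repeat {
      hit <- FALSE
      for (md in modifier_lexicon[order(-nchar(modifier_lexicon))]) {
        if (nchar(out) > nchar(md) && startsWith(out, md)) {
          out <- substring(out, nchar(md) + 1L)
          hit <- TRUE
          break
        }
      }
      if (!hit) break
    }
    out
  }
}

#' Surface head recall
#'
#' Fraction of reference terms whose head noun matches the head noun of
#' some dictionary term. Heads come from the reference's `head` column
#' where present, else from `head_extractor`; dictionary heads always
#' come from the extractor. Head matching credits productive term
#' formation (body part + problem, etc.) that exact surface matching
#' misses.
#'
#' @inheritParams surface_recall
#' @param head_extractor `function(term) -> head` used where explicit
#'   heads are absent.
#' @return list with `R_H`, `TP`, `N_ref`.
#' @export
head_recall <- function(dictionary, ref, head_extractor,
                        category = NULL) {
  ref <- ref_subset(ref, category)
  if (!nrow(ref)) stop("empty reference corpus", call. = FALSE)
  ref_heads <- ref$head
  need <- !nzchar(ref_heads)
  ref_heads[need] <- vapply(ref$surface[need], head_extractor, character(1))
  if (any(!nzchar(ref_heads))) {
    stop("empty head for reference term '",
         ref$surface[!nzchar(ref_heads)][1], "'", call. = FALSE)
  }
  dict_heads <- unique(vapply(unique(dictionary), head_extractor,
                              character(1)))
  if (length(dictionary) && any(!nzchar(dict_heads))) {
    stop("head extractor returned an empty head for a dictionary term",
         call. = FALSE)
  }
  TP <- sum(ref_heads %in% dict_heads)
  list(R_H = TP / nrow(ref), TP = TP, N_ref = nrow(ref))
}

#' Harmonic-mean F measure
#'
#' `F = 2PR / (P + R)`, defined as 0 when `P + R = 0`.
#' @param P,R precision and recall in `[0, 1]`.
#' @return the F value.
#' @export
f_measure <- function(P, R) {
  stopifnot(P >= 0, P <= 1, R >= 0, R <= 1)
  if (P + R == 0) 0 else 2 * P * R / (P + R)
}

#' Full evaluation report for a built dictionary
#'
#' Computes P, the three recalls, their F-measures, and (when `removed`
#' is non-empty) Err, keeping the integer counts behind every ratio.
#'
#' @param dictionary character vector of dictionary surfaces.
#' @param ref a `reference_corpus`.
#' @param truth_oracle oracle for P/Err (function or character set).
#' @param removed candidates removed by filtering (for Err; may be
#'   empty).
#' @param head_extractor head function for [head_recall()].
#' @param category restrict to one category (default: all).
#' @param n_sample sample size for P and Err.
#' @param rng_seed sampling seed.
#' @return object of class `evaluation_report`.
#' @export
evaluation_report <- function(dictionary, ref, truth_oracle,
                              removed = character(0),
                              head_extractor = function(x) x,
                              category = NULL, n_sample = 1000L,
                              rng_seed = 1L) {
  dictionary <- unique(dictionary)
  p <- precision_estimate(dictionary, truth_oracle, n_sample, rng_seed)
  rs <- surface_recall(dictionary, ref, category)
  ro <- object_recall(dictionary, ref, category)
  rh <- head_recall(dictionary, ref, head_extractor, category)
  err <- if (length(removed)) {
    err_estimate(removed, truth_oracle, n_sample,
                 derive_seed(rng_seed, "err"))
  } else {
    list(Err = NA_real_, M = NA_integer_, N = 0L)
  }
  structure(list(
    category = category %||% "ALL",
    P = p$P, P_counts = c(M = p$M, N = p$N),
    R_S = rs$R_S, R_S_counts = c(TP = rs$TP, N = rs$N_ref),
    R_O = ro$R_O, R_O_counts = c(TP = ro$TP, N = ro$N_obj),
    R_H = rh$R_H, R_H_counts = c(TP = rh$TP, N = rh$N_ref),
    F_S = f_measure(p$P, rs$R_S),
    F_O = f_measure(p$P, ro$R_O),
    F_H = f_measure(p$P, rh$R_H),
    Err = err$Err, Err_counts = c(M = err$M, N = err$N)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("<evaluation_report>", x$category, "\n")
  row <- c(P = x$P, R_O = x$R_O, R_S = x$R_S, R_H = x$R_H,
           F_O = x$F_O, F_S = x$F_S, F_H = x$F_H, Err = x$Err)
  print(round(row, digits))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report an `evaluation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
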