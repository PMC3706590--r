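# Snippet analysis: contextual n-gram patterns mined from seed snippets,
# a TF/IDF-like pattern effectiveness score, and a Bernoulli naive Bayes
# classifier over the top patterns. The same naive Bayes is reused by the
# affix filter.

#' Tokenize a snippet context for pattern mining
#'
#' English contexts are lowercased word tokens; Chinese contexts are
#' character tokens, so Chinese patterns are character n-grams.
#' @param text character scalar.
#' @param language `"en"` or `"zh"`.
#' @return character vector of tokens.
#' @export
tokenize_context <- function(text, language = c("en", "zh")) {
  language <- check_language(language)
  text <- normalize_term(text, language)
  if (!nzchar(text)) return(character(0))
  if (language == "en") {
    toks <- strsplit(text, " ", fixed = TRUE)[[1]]
    toks[nzchar(toks)]
  } else {
    ch <- strsplit(gsub(" ", "", text, fixed = TRUE), "", fixed = TRUE)[[1]]
    ch
  }
}

#' @noRd
ngrams_from <- function(tokens, max_n = 5L) {
  n <- length(tokens)
  if (!n) return(character(0))
  out <- character(0)
  for (len in seq_len(min(max_n, n))) {
    out <- c(out, paste(tokens[seq_len(len)], collapse = " "))
  }
  out
}

#' Extract boundary contextual patterns for a term from its snippets
#'
#' A contextual pattern is an n-gram (n = 1..5) immediately following the
#' query term when the term sits at the very beginning of a snippet
#' context, or immediately preceding it when the term sits at the very
#' end. Occurrences of the term elsewhere in the context yield nothing:
#' restricting to context boundaries sidesteps term-boundary detection.
#'
#' @param snips data.frame of snippets (needs a `context` column).
#' @param term normalized query term.
#' @param language `"en"` or `"zh"`.
#' @return data.frame with columns `tokens` (space-joined) and `side`
#'   (`"follows"` or `"precedes"`), one row per extracted occurrence.
#' @export
extract_patterns <- function(snips, term, language = c("en", "zh")) {
  language <- check_language(language)
  term_toks <- tokenize_context(term, language)
  nt <- length(term_toks)
  toks_out <- character(0)
  side_out <- character(0)
  if (nt > 0L) {
    for (ctx in snips$context) {
      toks <- tokenize_context(ctx, language)
      n <- length(toks)
      if (n <= nt) next
      if (identical(toks[seq_len(nt)], term_toks)) {
        rest <- toks[(nt + 1L):n]
        gs <- ngrams_from(rest)
        toks_out <- c(toks_out, gs)
        side_out <- c(side_out, rep("follows", length(gs)))
      }
      if (identical(toks[(n - nt + 1L):n], term_toks)) {
        rest <- rev(toks[seq_len(n - nt)])
        gs <- ngrams_from(rest)
        # reverse each n-gram back to reading order
        gs <- vapply(strsplit(gs, " ", fixed = TRUE),
                     function(g) paste(rev(g), collapse = " "), character(1))
        toks_out <- c(toks_out, gs)
        side_out <- c(side_out, rep("precedes", length(gs)))
      }
    }
  }
  data.frame(tokens = toks_out, side = side_out, stringsAsFactors = FALSE)
}

#' Score the effectiveness of a contextual pattern
#'
#' For a pattern with `N_p` occurrences on in-class seed snippets, `O`
#' seed terms in the other two classes, and `N_o` of those other-class
#' seeds showing the pattern at least once, the score is
#' `N_p * log((O + 1) / (N_o + 1))` -- a TF/IDF-like trade-off that grows
#' with in-class evidence and shrinks toward zero as the pattern becomes
#' ubiquitous in the other classes.
#'
#' @param N_p in-class occurrence count(s).
#' @param O number of other-class seed terms (scalar, > 0).
#' @param N_o number of other-class seeds with >= 1 occurrence.
#' @return numeric score(s).
#' @export
score_pattern <- function(N_p, O, N_o) {
  if (length(O) != 1L || O <= 0) {
    stop("O must be a single positive count (other-class seeds required)",
         call. = FALSE)
  }
  stopifnot(all(N_p >= 0), all(N_o >= 0), all(N_o <= O))
  N_p * log((O + 1) / (N_o + 1))
}

#' Mine and score contextual patterns for one category
#'
#' Extracts boundary patterns from the snippets of every in-class seed,
#' totals in-class occurrences (`N_p`), counts the other-class seeds
#' showing each pattern (`N_o`), and scores with [score_pattern()].
#'
#' @param store a [snippet_store()].
#' @param seeds a [seed_dictionary()].
#' @param category category whose patterns are mined.
#' @param language `"en"` or `"zh"`.
#' @param max_snippets snippets consulted per term (default 100).
#' @return data.frame `tokens`, `side`, `N_p`, `N_o`, `score`, sorted by
#'   decreasing score.
#' @export
mine_patterns <- function(store, seeds, category, language = c("en", "zh"),
                          max_snippets = 100L) {
  language <- check_language(language)
  check_category(category)
  in_terms <- seeds$entries[[category]]
  other <- unlist(seeds$entries[setdiff(CATEGORIES, category)],
                  use.names = FALSE)
  O <- length(other)
  if (O == 0L) stop("no other-class seeds; cannot score patterns",
                    call. = FALSE)
  key <- function(df) paste(df$side, df$tokens, sep = "\r")
  np <- new.env(parent = emptyenv())
  for (tm in in_terms) {
    pats <- extract_patterns(fetch_snippets(store, tm, max_snippets), tm,
                             language)
    for (kk in key(pats)) np[[kk]] <- (np[[kk]] %||% 0L) + 1L
  }
  if (!length(ls(np))) {
    return(data.frame(tokens = character(0), side = character(0),
                      N_p = integer(0), N_o = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  no <- new.env(parent = emptyenv())
  for (tm in other) {
    pats <- extract_patterns(fetch_snippets(store, tm, max_snippets), tm,
                             language)
    for (kk in unique(key(pats))) no[[kk]] <- (no[[kk]] %||% 0L) + 1L
  }
  keys <- sort(ls(np), method = "radix")
  parts <- strsplit(keys, "\r", fixed = TRUE)
  df <- data.frame(
    tokens = vapply(parts, `[`, character(1), 2L),
    side = vapply(parts, `[`, character(1), 1L),
    N_p = vapply(keys, function(kk) as.integer(np[[kk]]), integer(1)),
    N_o = vapply(keys, function(kk) as.integer(no[[kk]] %||% 0L), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  df$score <- score_pattern(df$N_p, O, df$N_o)
  df[order(-df$score, -df$N_p, df$tokens, df$side, method = "radix"), ,
     drop = FALSE]
}

#' Keep the top-m patterns by score
#'
#' Ties are broken by higher `N_p`, then lexicographically on tokens, so
#' the selection is deterministic regardless of input order. If fewer
#' than `m` patterns exist, all are returned with a warning.
#'
#' @param scored data.frame as from [mine_patterns()].
#' @param m number of patterns to keep (default 50).
#' @return the top-m rows.
#' @export
select_top_patterns <- function(scored, m = 50L) {
  stopifnot(m >= 1L)
  if (nrow(scored) < m) {
    warning("only ", nrow(scored), " patterns available (requested ", m, ")",
            call. = FALSE)
  }
  ord <- order(-scored$score, -scored$N_p, scored$tokens, scored$side,
               method = "radix")
  utils::head(scored[ord, , drop = FALSE], m)
}

#' Binary featurization of a term against a pattern set
#'
#' Feature j is 1 iff at least one of the term's snippets yields pattern
#' j at its required side (the same adjacency rule the mining step uses),
#' else 0. A term with no snippets maps to the all-zero vector.
#'
#' @param term normalized candidate surface.
#' @param snips data.frame of its snippets.
#' @param patterns data.frame with `tokens` and `side` columns (the
#'   feature dimension).
#' @param language `"en"` or `"zh"`.
#' @param loose if `TRUE`, a feature fires whenever the context contains
#'   the n-gram anywhere (no side/adjacency requirement).
#' @return integer 0/1 vector of length `nrow(patterns)`.
#' @export
featurize <- function(term, snips, patterns, language = c("en", "zh"),
                      loose = FALSE) {
  language <- check_language(language)
  feat_key <- paste(patterns$side, patterns$tokens, sep = "\r")
  if (!NROW(snips)) return(integer(length(feat_key)))
  if (loose) {
    hit <- logical(length(feat_key))
    for (ctx in snips$context) {
      toks <- tokenize_context(ctx, language)
      joined <- paste(toks, collapse = " ")
      hit <- hit | vapply(patterns$tokens, function(p) {
        grepl(p, joined, fixed = TRUE)
      }, logical(1))
    }
    return(as.integer(hit))
  }
  got <- extract_patterns(snips, term, language)
  as.integer(feat_key %in% paste(got$side, got$tokens, sep = "\r"))
}

#' Train a Bernoulli naive Bayes classifier
#'
#' Class priors are the class proportions; per-feature conditionals are
#' Laplace-smoothed as `(count + alpha) / (n_class + 2 * alpha)`, so all
#' conditionals lie strictly inside (0, 1).
#'
#' @param pos,neg matrices (rows = instances) of 0/1 features.
#' @param alpha smoothing pseudo-count (default 1).
#' @param feature_names optional feature labels.
#' @return object of class `naive_bayes_model`.
#' @export
nb_train <- function(pos, neg, alpha = 1.0, feature_names = NULL) {
  pos <- as.matrix(pos)
  neg <- as.matrix(neg)
  if (!nrow(pos) || !nrow(neg)) {
    stop("both classes need at least one training instance", call. = FALSE)
  }
  if (ncol(pos) != ncol(neg)) {
    stop("positive and negative feature dimensions differ", call. = FALSE)
  }
  n_pos <- nrow(pos)
  n_neg <- nrow(neg)
  structure(list(
    feature_names = feature_names %||% paste0("f", seq_len(ncol(pos))),
    prior_pos = n_pos / (n_pos + n_neg),
    prior_neg = n_neg / (n_pos + n_neg),
    cond_pos = (colSums(pos) + alpha) / (n_pos + 2 * alpha),
    cond_neg = (colSums(neg) + alpha) / (n_neg + 2 * alpha),
    alpha = alpha), class = "naive_bayes_model")
}

#' @export
print.naive_bayes_model <- function(x, ...) {
  cat("<naive_bayes_model>", length(x$cond_pos), "binary features,",
      "prior(+) =", signif(x$prior_pos, 4), "\n")
  invisible(x)
}

#' Posterior probability of the positive class
#'
#' Exact Bernoulli naive Bayes posterior, computed in log space for
#' numerical stability.
#'
#' @param model a `naive_bayes_model`.
#' @param x 0/1 feature vector of matching dimension.
#' @return probability in `[0, 1]`.
#' @export
nb_posterior <- function(model, x) {
  stopifnot(inherits(model, "naive_bayes_model"))
  if (length(x) != length(model$cond_pos)) {
    stop("feature vector has length ", length(x), ", model expects ",
         length(model$cond_pos), call. = FALSE)
  }
  x <- as.numeric(x)
  lp <- log(model$prior_pos) +
    sum(x * log(model$cond_pos) + (1 - x) * log1p(-model$cond_pos))
  ln <- log(model$prior_neg) +
    sum(x * log(model$cond_neg) + (1 - x) * log1p(-model$cond_neg))
  m <- max(lp, ln)
  exp(lp - m) / (exp(lp - m) + exp(ln - m))
}

#' Classify pool candidates by snippet context
#'
#' Each candidate is featurized against the category's top patterns from
#' its own snippets and accepted iff the naive Bayes posterior reaches
#' `threshold`. Candidates without snippets are scored on the all-zero
#' vector (for an informative model, absence of category context is
#' negative evidence). The returned sets partition the pool.
#'
#' @param pool a `candidate_pool`.
#' @param store a [snippet_store()].
#' @param patterns top-pattern data.frame for the pool's category.
#' @param model trained `naive_bayes_model` for the category.
#' @param threshold acceptance posterior (default 0.5).
#' @param language `"en"` or `"zh"`.
#' @return `list(accepted =, rejected =)` character vectors.
#' @export
classify_candidates <- function(pool, store, patterns, model,
                                threshold = 0.5, language = c("en", "zh")) {
  language <- check_language(language)
  surfaces <- names(pool$terms)
  post <- vapply(surfaces, function(tm) {
    nb_posterior(model, featurize(tm, fetch_snippets(store, tm), patterns,
                                  language))
  }, numeric(1))
  list(accepted = surfaces[post >= threshold],
       rejected = surfaces[post < threshold])
}

#' Write/read a pattern set as TSV
#'
#' Columns: `tokens`, `side`, `N_p`, `N_o`, `score`.
#' @param patterns pattern data.frame.
#' @param path file path.
#' @return `path` / the pattern data.frame.
#' @export
write_patterns <- function(patterns, path) {
  utils::write.table(
    patterns[, c("tokens", "side", "N_p", "N_o", "score")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Save/load a naive Bayes model as JSON (exact round-trip)
#' @param model a `naive_bayes_model`.
#' @param path file path.
#' @return `path` / the model.
#' @export
nb_save <- function(model, path) {
  payload <- unclass(model)
  payload$cond_pos <- unname(payload$cond_pos)
  payload$cond_neg <- unname(payload$cond_neg)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname nb_save
#' @export
nb_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(feature_names = p$feature_names,
                 prior_pos = p$prior_pos, prior_neg = p$prior_neg,
                 cond_pos = p$cond_pos, cond_neg = p$cond_neg,
                 alpha = p$alpha), class = "naive_bayes_model")
}
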