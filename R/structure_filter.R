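# Form-based filtering: length fitness f, list quality S_q, wholesale
# list acceptance, POS gate g, affix classifier A, entity score S(E), and
# the combined accept/delete/defer gate.

#' Length-fitness parameters
#'
#' `l_p` is the "proper" length of an in-domain term: 5 characters for
#' Chinese, 2 words for English (most clinical terms are 3-5 Chinese
#' characters or 1-3 English words). The decay rate `c` is calibrated so
#' that the fitness at twice the proper length equals `f_floor`:
#' `f(2 * l_p) = f_floor`, i.e. `c = -log(f_floor) / l_p`.
#'
#' @param language `"en"` or `"zh"` (sets the default `l_p`).
#' @param l_p proper length override.
#' @param f_floor fitness at `2 * l_p` (default 0.1).
#' @return object of class `length_params`.
#' @export
length_params <- function(language = c("en", "zh"),
                          l_p = if (match.arg(language) == "en") 2 else 5,
                          f_floor = 0.1) {
  stopifnot(l_p >= 1, f_floor > 0, f_floor < 1)
  structure(list(l_p = l_p, f_floor = f_floor, c = -log(f_floor) / l_p),
            class = "length_params")
}

#' Length fitness of a term or list
#'
#' `f(l) = 1` for `l <= l_p` and `exp(-c * (l - l_p))` beyond: a fast
#' exponential decay that punishes entries too long for the domain (long
#' entries tend to be sentence fragments, not terminology). Continuous at
#' `l_p`, strictly decreasing after it, never 0.
#'
#' @param l length(s); English words or Chinese characters, possibly
#'   fractional for list averages.
#' @param params a [length_params()].
#' @return fitness value(s) in `(0, 1]`.
#' @export
length_fitness <- function(l, params) {
  stopifnot(inherits(params, "length_params"))
  ifelse(l <= params$l_p, 1, exp(-params$c * (l - params$l_p)))
}

#' Quality score of a candidate list
#'
#' `S_q(L) = (H_L / log2(2 + N_L)) * f(mean_len)`: linear in the hit
#' count but only logarithmic in list size, because a list's hit count
#' matters more than its length, damped by the length fitness of its
#' average item. Zero iff the list holds no seed terms.
#'
#' @param l a `candidate_list` with `H_L` populated (see
#'   [select_lists()]).
#' @param params a [length_params()].
#' @return numeric score `>= 0`.
#' @export
list_score <- function(l, params) {
  (l$H_L / log2(2 + l$N_L)) * length_fitness(l$mean_len, params)
}

#' Gate configuration for the combined system
#'
#' @param top_lists number of top-quality lists ranked (default 200).
#' @param min_list_entities a ranked list is admitted wholesale only if
#'   its item count exceeds this (default 100, strictly greater).
#' @param accept_top_entities entities accepted outright by score rank
#'   before snippet analysis (default 0: rely on wholesale lists).
#' @param delete_below entities scoring strictly below this are deleted
#'   without snippet processing; `NULL` means "use the 25th percentile of
#'   the scored entities at run time".
#' @return object of class `gate_config`.
#' @export
gate_config <- function(top_lists = 200L, min_list_entities = 100L,
                        accept_top_entities = 0L, delete_below = NULL) {
  stopifnot(top_lists >= 0L, min_list_entities >= 0L,
            accept_top_entities >= 0L)
  if (!is.null(delete_below) && delete_below < 0) {
    stop("delete_below must be >= 0", call. = FALSE)
  }
  structure(list(top_lists = top_lists,
                 min_list_entities = min_list_entities,
                 accept_top_entities = accept_top_entities,
                 delete_below = delete_below), class = "gate_config")
}

#' Select the highest-quality lists for wholesale acceptance
#'
#' Ranks all lists by `S_q` (ties: higher `H_L`, then `list_id`), keeps
#' the top `cfg$top_lists`, and of those retains only lists whose item
#' count is strictly greater than `cfg$min_list_entities`. Every item of
#' a retained list is accepted as a term without further filtering --
#' this is what recovers terms too rare for snippet analysis.
#'
#' @param lists selected, cleaned `candidate_list` objects.
#' @param params a [length_params()].
#' @param cfg a [gate_config()].
#' @return the retained lists, each with its score in `$S_q`.
#' @export
select_quality_lists <- function(lists, params, cfg = gate_config()) {
  if (!length(lists)) return(list())
  sq <- vapply(lists, list_score, numeric(1), params = params)
  hl <- vapply(lists, function(l) l$H_L, numeric(1))
  id <- vapply(lists, function(l) l$list_id, character(1))
  ord <- order(-sq, -hl, id, method = "radix")
  keep <- utils::head(ord, cfg$top_lists)
  out <- list()
  for (i in keep) {
    if (lists[[i]]$N_L > cfg$min_list_entities) {
      l <- lists[[i]]
      l$S_q <- sq[[i]]
      out[[length(out) + 1L]] <- l
    }
  }
  out
}

# ---------------------------------------------------------------------
# POS gate

#' POS tags that disqualify a candidate
#'
#' Pronouns, particles (of/up/down/off), and question words never occur
#' inside well-formed clinical terms, which consist of nouns and
#' adjectives.
#' @export
FORBIDDEN_POS <- c("PRP", "RP", "WP", "WRB")

#' @noRd
toy_tagger_lexicon <- function() {
  list(
    PRP = c("i", "you", "he", "she", "it", "we", "they", "his", "her",
            "him", "them", "their", "its", "your", "my", "our",
            "他", "她", "它", "我", "你"),
    RP = c("of", "up", "down", "off", "out", "over"),
    WP = c("what", "who", "whom", "which"),
    WRB = c("how", "when", "where", "why",
            "怎么", "如何"))
}

#' Deterministic lexicon-based POS tagger
#'
#' A minimal tagger satisfying the tagger contract (tokens in, Penn-style
#' tags out, tagset covering at least NN/PRP/RP/WP/WRB): closed-class
#' words are looked up in a small lexicon, everything else is tagged NN.
#' Production taggers can be plugged into the pipeline in its place via
#' any `function(tokens) -> tags`.
#'
#' @param tokens character vector of tokens.
#' @return character vector of tags, same length.
#' @export
toy_pos_tagger <- function(tokens) {
  lex <- toy_tagger_lexicon()
  tags <- rep("NN", length(tokens))
  low <- tolower(tokens)
  for (tag in names(lex)) tags[low %in% lex[[tag]]] <- tag
  tags
}

#' POS gate g over a tagged candidate
#'
#' Returns 0 iff any tag is a pronoun (PRP), particle (RP), or question
#' word (WP, WRB); otherwise 1. An empty token sequence is vacuously
#' clean.
#'
#' @param tags character vector of POS tags (or a data.frame whose
#'   second column holds tags).
#' @return 0 or 1.
#' @export
pos_gate <- function(tags) {
  if (is.data.frame(tags)) tags <- tags[[2]]
  as.integer(!any(tags %in% FORBIDDEN_POS))
}

# ---------------------------------------------------------------------
# Affix features

#' @noRd
affix_candidates <- function(term, language) {
  if (language == "en") {
    s <- gsub("[^a-z]", "", tolower(term))
    max_n <- 5L
  } else {
    s <- gsub(" ", "", term, fixed = TRUE)
    max_n <- 3L
  }
  n <- nchar(s)
  if (!n) return(data.frame(affix = character(0), position = character(0)))
  lens <- seq_len(min(max_n, n))
  data.frame(
    affix = c(substring(s, 1L, lens), substring(s, n - lens + 1L, n)),
    position = rep(c("prefix", "suffix"), each = length(lens)),
    stringsAsFactors = FALSE)
}

#' Extract the top affix features of a category's seed set
#'
#' Medical terminology has strong affix conventions (English tests end in
#' "-scopy", inflammations in "-itis"; Chinese drug names end in
#' capsule/tablet characters). Candidate affixes are all prefixes and
#' suffixes of length 1-5 English letters (non-letters stripped,
#' lowercased) or 1-3 Chinese characters, ranked by the number of seeds
#' carrying them (descending; ties broken lexicographically), and the top
#' `m` become binary features.
#'
#' @param seeds a [seed_dictionary()].
#' @param category one of `CATEGORIES`.
#' @param language `"en"` or `"zh"`.
#' @param m number of affix features kept (default 20).
#' @return object of class `affix_feature_set`: data.frame `affix`,
#'   `position`, `freq` with a `language` attribute.
#' @export
extract_affix_features <- function(seeds, category,
                                   language = c("en", "zh"), m = 20L) {
  language <- check_language(language)
  check_category(category)
  terms <- seeds$entries[[category]]
  if (!length(terms)) stop("no seeds in category ", category, call. = FALSE)
  tab <- new.env(parent = emptyenv())
  for (tm in terms) {
    cand <- affix_candidates(tm, language)
    for (kk in unique(paste(cand$position, cand$affix, sep = "\r"))) {
      tab[[kk]] <- (tab[[kk]] %||% 0L) + 1L
    }
  }
  keys <- sort(ls(tab), method = "radix")
  parts <- strsplit(keys, "\r", fixed = TRUE)
  df <- data.frame(
    affix = vapply(parts, `[`, character(1), 2L),
    position = vapply(parts, `[`, character(1), 1L),
    freq = vapply(keys, function(kk) as.integer(tab[[kk]]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$freq, df$position, df$affix, method = "radix"), ,
           drop = FALSE]
  df <- utils::head(df, m)
  rownames(df) <- NULL
  affix_feature_set(df, language)
}

#' Construct an affix feature set directly
#'
#' @param features data.frame with columns `affix` and `position`
#'   (`"prefix"` or `"suffix"`); a `freq` column is optional.
#' @param language `"en"` or `"zh"`.
#' @return object of class `affix_feature_set`.
#' @export
affix_feature_set <- function(features, language = c("en", "zh")) {
  language <- check_language(language)
  stopifnot(all(c("affix", "position") %in% names(features)),
            all(features$position %in% c("prefix", "suffix")),
            all(nzchar(features$affix)))
  structure(as.data.frame(features), language = language,
            class = c("affix_feature_set", "data.frame"))
}

#' Binary affix featurization of a term
#'
#' Feature j is 1 iff the term starts with (prefix) or ends with (suffix)
#' affix j, measured on the same canonical string affixes were built
#' from: English terms are reduced to lowercase letters, Chinese terms to
#' their space-free character string. The word "gastroscopy", for
#' example, fires both a "-scopy" and a "-copy" suffix feature but not
#' "-ia".
#'
#' @param term surface string.
#' @param feats an `affix_feature_set`.
#' @return integer 0/1 vector of length `nrow(feats)`.
#' @export
affix_featurize <- function(term, feats) {
  stopifnot(inherits(feats, "affix_feature_set"))
  language <- attr(feats, "language")
  s <- if (language == "en") gsub("[^a-z]", "", tolower(term)) else
    gsub(" ", "", term, fixed = TRUE)
  n <- nchar(s)
  vapply(seq_len(nrow(feats)), function(j) {
    a <- feats$affix[[j]]
    if (nchar(a) > n) return(0L)
    hit <- if (feats$position[[j]] == "prefix") {
      substring(s, 1L, nchar(a)) == a
    } else {
      substring(s, n - nchar(a) + 1L, n) == a
    }
    as.integer(hit)
  }, integer(1))
}

#' Train the affix naive Bayes classifier for one category
#'
#' Positives are the category's seeds; negatives are sampled uniformly
#' (seeded) from items of candidate lists containing no seed terms at
#' all, the same negative source the snippet classifier uses. The sample
#' size matches the positive count.
#'
#' @param seeds a [seed_dictionary()].
#' @param category one of `CATEGORIES`.
#' @param feats an `affix_feature_set` for the category.
#' @param negatives character vector of negative surfaces (items of
#'   zero-hit lists).
#' @param alpha Laplace smoothing (default 1).
#' @param rng_seed seed for negative sampling.
#' @return a `naive_bayes_model`.
#' @export
train_affix_model <- function(seeds, category, feats, negatives,
                              alpha = 1.0, rng_seed = 1L) {
  check_category(category)
  pos_terms <- seeds$entries[[category]]
  if (!length(pos_terms)) stop("no positive seeds", call. = FALSE)
  negatives <- unique(negatives)
  if (!length(negatives)) stop("no negative candidates", call. = FALSE)
  n_neg <- min(length(negatives), length(pos_terms))
  neg_terms <- with_seed(rng_seed, sample(negatives, n_neg))
  pos <- t(vapply(pos_terms, affix_featurize, integer(nrow(feats)),
                  feats = feats))
  neg <- t(vapply(neg_terms, affix_featurize, integer(nrow(feats)),
                  feats = feats))
  nb_train(pos, neg, alpha = alpha,
           feature_names = paste(feats$position, feats$affix, sep = ":"))
}

#' Affix confidence A of a candidate
#'
#' The positive-class posterior of the affix naive Bayes for the
#' candidate's affix feature vector.
#'
#' @param term surface string.
#' @param model trained affix `naive_bayes_model`.
#' @param feats the `affix_feature_set` the model was trained on.
#' @return probability in `[0, 1]`.
#' @export
affix_confidence <- function(term, model, feats) {
  nb_posterior(model, affix_featurize(term, feats))
}

# ---------------------------------------------------------------------
# Entity score and combined gate

#' Combined form-based score of a candidate entity
#'
#' `S(E) = f(l_E) * g(C_E) * A(C_E) * sum_i S_q(L_i)` over the M lists
#' the entity appears on: the quality mass of its lists, gated by length
#' fitness, the POS gate, and affix confidence. Zero iff the POS gate
#' fires or all list scores are zero; adding a list never lowers the
#' score.
#'
#' @param term surface string.
#' @param list_scores numeric vector of `S_q` for the term's lists
#'   (length M >= 1).
#' @param f_val,g_val,A_val component values.
#' @param agg `"sum"` (default) or `"max"` aggregation over lists.
#' @return object of class `entity_score` (a list with `term`, `M`,
#'   `list_quality_sum`, `f_val`, `g_val`, `A_val`, `S_E`).
#' @export
entity_score <- function(term, list_scores, f_val, g_val, A_val,
                         agg = c("sum", "max")) {
  agg <- match.arg(agg)
  stopifnot(length(list_scores) >= 1L, g_val %in% c(0L, 1L),
            f_val > 0, f_val <= 1, A_val >= 0, A_val <= 1)
  mass <- if (agg == "sum") sum(list_scores) else max(list_scores)
  structure(list(term = term, M = length(list_scores),
                 list_quality_sum = mass, f_val = f_val, g_val = g_val,
                 A_val = A_val, S_E = f_val * g_val * A_val * mass),
            class = "entity_score")
}

#' Score every pool candidate with the combined form-based score
#'
#' Computes, per candidate: M and the `S_q` mass of its source lists
#' (via provenance), length fitness of its own length, the POS gate over
#' its tokens, and affix confidence; then combines them with
#' [entity_score()].
#'
#' @param pool a `candidate_pool`.
#' @param lists the selected, cleaned `candidate_list` objects the pool
#'   was aggregated from.
#' @param params a [length_params()].
#' @param affix_model,affix_feats affix classifier and its feature set.
#' @param language `"en"` or `"zh"`.
#' @param tagger a `function(tokens) -> tags` (default
#'   [toy_pos_tagger()]).
#' @param agg list aggregation, `"sum"` or `"max"`.
#' @return data.frame `term`, `M`, `f`, `g`, `A`, `sum_Sq`, `S_E`.
#' @export
score_entities <- function(pool, lists, params, affix_model, affix_feats,
                           language = c("en", "zh"),
                           tagger = toy_pos_tagger, agg = "sum") {
  language <- check_language(language)
  sq <- stats::setNames(
    vapply(lists, list_score, numeric(1), params = params),
    vapply(lists, function(l) l$list_id, character(1)))
  surfaces <- names(pool$terms)
  n <- length(surfaces)
  out <- data.frame(term = surfaces, M = integer(n), f = numeric(n),
                    g = integer(n), A = numeric(n), sum_Sq = numeric(n),
                    S_E = numeric(n), stringsAsFactors = FALSE,
                    row.names = NULL)
  for (i in seq_len(n)) {
    tm <- surfaces[[i]]
    src_lists <- vapply(pool$terms[[tm]]$sources, `[`, character(1), 2L)
    scores <- unname(sq[src_lists])
    scores[is.na(scores)] <- 0
    toks <- if (language == "en") {
      strsplit(tm, " ", fixed = TRUE)[[1]]
    } else {
      tokenize_context(tm, "zh")
    }
    es <- entity_score(
      tm, scores,
      f_val = length_fitness(max(term_length(tm, language), 1), params),
      g_val = pos_gate(tagger(toks)),
      A_val = affix_confidence(tm, affix_model, affix_feats),
      agg = agg)
    out$M[[i]] <- es$M
    out$f[[i]] <- es$f_val
    out$g[[i]] <- es$g_val
    out$A[[i]] <- es$A_val
    out$sum_Sq[[i]] <- es$list_quality_sum
    out$S_E[[i]] <- es$S_E
  }
  out
}

#' Partition scored candidates into accepted / deleted / deferred
#'
#' Wholesale-list terms plus the `accept_top_entities` highest-scoring
#' candidates are accepted outright; candidates scoring strictly below
#' `delete_below` are deleted without snippet processing; the remainder
#' is deferred to snippet classification. The three sets partition the
#' union of the scored candidates and the wholesale terms. When
#' `cfg$delete_below` is `NULL` the threshold is the 25th percentile of
#' the non-wholesale scores (reported in the result).
#'
#' @param scored data.frame from [score_entities()].
#' @param wholesale_terms character vector from the items of
#'   [select_quality_lists()] output.
#' @param cfg a [gate_config()].
#' @return `list(accepted =, deleted =, deferred =, delete_below =)`.
#' @export
combined_gate <- function(scored, wholesale_terms, cfg = gate_config()) {
  wholesale_terms <- unique(wholesale_terms)
  rest <- scored[!scored$term %in% wholesale_terms, , drop = FALSE]
  ord <- order(-rest$S_E, rest$term, method = "radix")
  rest <- rest[ord, , drop = FALSE]
  top <- utils::head(rest$term, cfg$accept_top_entities)
  pool_rest <- rest[!rest$term %in% top, , drop = FALSE]
  delete_below <- if (nrow(pool_rest)) {
    cfg$delete_below %||%
      unname(stats::quantile(pool_rest$S_E, 0.25, type = 7, names = FALSE))
  } else {
    cfg$delete_below %||% 0
  }
  deleted <- pool_rest$term[pool_rest$S_E < delete_below]
  deferred <- pool_rest$term[pool_rest$S_E >= delete_below]
  list(accepted = sort(union(wholesale_terms, top), method = "radix"),
       deleted = sort(deleted, method = "radix"),
       deferred = sort(deferred, method = "radix"),
       delete_below = delete_below)
}

#' Dump entity scores and gate decisions as TSV
#'
#' Columns: `term`, `M`, `f`, `g`, `A`, `sum_Sq`, `S_E`,
#' `gate_decision`.
#' @param scored data.frame from [score_entities()].
#' @param gate result of [combined_gate()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_entity_scores <- function(scored, gate, path) {
  scored$gate_decision <- ifelse(
    scored$term %in% gate$accepted, "accept",
    ifelse(scored$term %in% gate$deleted, "delete", "defer"))
  utils::write.table(scored, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
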