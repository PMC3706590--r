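# Orchestration: the baseline (snippet-only) and combined (weighted)
# dictionary-expansion systems, iterative re-seeding, and run-level
# evaluation.

#' Configuration of a pipeline run
#'
#' Collects every stage parameter in one validated object that is
#' persisted alongside outputs: the stores, the seed dictionary, the
#' list-selection threshold `k`, length-fitness settings, pattern/affix
#' feature counts, the combined-system gate, the snippet-classifier
#' threshold, the iteration budget, and the master RNG seed (all
#' stage-level draws are derived from it deterministically).
#'
#' @param language `"en"` or `"zh"`.
#' @param seeds a [seed_dictionary()] (or path to a seeds TSV).
#' @param manifest_path page-store manifest JSONL.
#' @param snippets_path snippet-store JSONL.
#' @param system `"combined"` (default) or `"baseline"`.
#' @param categories categories to expand (default all three).
#' @param max_pairs query pairs issued per category and iteration.
#' @param k list-selection hit-count threshold (strictly greater).
#' @param max_len cleanup length cap (default `3 * l_p`).
#' @param punct_set cleanup punctuation set.
#' @param f_floor length-fitness floor at twice the proper length.
#' @param m_patterns contextual patterns per category (default 50).
#' @param m_affixes affix features per category (default 20).
#' @param gate a [gate_config()].
#' @param nb_threshold snippet-classifier acceptance posterior.
#' @param alpha naive Bayes smoothing.
#' @param max_iterations re-seeding iterations (default 2).
#' @param rng_seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(language = c("en", "zh"), seeds, manifest_path,
                       snippets_path, system = c("combined", "baseline"),
                       categories = CATEGORIES, max_pairs = 5000L,
                       k = 10L,
                       max_len = if (match.arg(language) == "en") 6L else 15L,
                       punct_set = default_punct_set(), f_floor = 0.1,
                       m_patterns = 50L, m_affixes = 20L,
                       gate = gate_config(), nb_threshold = 0.5,
                       alpha = 1.0, max_iterations = 2L, rng_seed = 1L) {
  language <- match.arg(language)
  system <- match.arg(system)
  if (is.character(seeds)) seeds <- load_dictionary(seeds, language)
  stopifnot(inherits(seeds, "seed_dictionary"),
            all(categories %in% CATEGORIES),
            file.exists(manifest_path), file.exists(snippets_path),
            max_pairs >= 1L, k >= 0L, max_len >= 1L,
            m_patterns >= 1L, m_affixes >= 1L,
            inherits(gate, "gate_config"),
            nb_threshold >= 0, nb_threshold <= 1,
            max_iterations >= 1L)
  structure(list(
    language = language, seeds = seeds, manifest_path = manifest_path,
    snippets_path = snippets_path, system = system,
    categories = categories, max_pairs = as.integer(max_pairs),
    k = as.integer(k), max_len = as.integer(max_len),
    punct_set = punct_set, f_floor = f_floor,
    m_patterns = as.integer(m_patterns),
    m_affixes = as.integer(m_affixes), gate = gate,
    nb_threshold = nb_threshold, alpha = alpha,
    max_iterations = as.integer(max_iterations),
    rng_seed = as.integer(rng_seed)), class = "run_config")
}

#' @noRd
pool_subset <- function(pool, surfaces) {
  structure(list(category = pool$category,
                 terms = pool$terms[names(pool$terms) %in% surfaces]),
            class = "candidate_pool")
}

#' Run the dictionary-expansion pipeline
#'
#' Per iteration and category: issue two-seed queries, fetch the matched
#' pages, group text nodes into candidate lists, select lists with more
#' than `k` seed hits, clean them, and aggregate the surviving items
#' into a candidate pool. The baseline system then classifies every
#' candidate by snippet context alone. The combined system first admits
#' the items of the highest-quality big lists wholesale, scores the
#' remaining candidates with the form-based entity score, deletes the
#' lowest-scoring ones without snippet processing, and sends only the
#' rest to the snippet classifier. Accepted terms are merged into the
#' seed dictionary and serve as seeds in the next iteration; the run
#' stops when an iteration adds nothing or `max_iterations` is reached.
#'
#' Contextual patterns, the snippet classifier, and the affix classifier
#' are trained once per category, on the initial high-precision seeds
#' (negatives sampled from lists containing no seed terms).
#'
#' @param cfg a [run_config()].
#' @return list with `dictionary` (the expanded [seed_dictionary()]),
#'   `seeds` (the initial one), `removed` (per-category character
#'   vectors of discarded candidates), `report` (per-stage count
#'   data.frame), and `models` (per-category patterns and classifiers).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  pstore <- page_store(cfg$manifest_path)
  sstore <- snippet_store(cfg$snippets_path)
  params <- length_params(cfg$language, f_floor = cfg$f_floor)
  seeds <- cfg$seeds
  removed <- stats::setNames(
    replicate(length(cfg$categories), character(0), simplify = FALSE),
    cfg$categories)
  models <- list()
  rows <- list()
  for (iter in seq_len(cfg$max_iterations)) {
    added_any <- FALSE
    for (cat in cfg$categories) {
      stage <- function(name) {
        derive_seed(cfg$rng_seed, paste(name, cat, iter, sep = "-"))
      }
      pairs <- generate_query_pairs(seeds, cat, cfg$max_pairs,
                                    stage("pairs"))
      pages <- fetch_pages(pstore, pairs)
      lists <- list()
      for (pg in pages) {
        lists <- c(lists,
                   extract_candidate_lists(pg$html, pg$page_id,
                                           cfg$language))
      }
      seed_set <- seeds$entries[[cat]]
      selected <- select_lists(lists, seed_set, cfg$k)
      cleaned <- lapply(selected, clean_list, language = cfg$language,
                        max_len = cfg$max_len, punct_set = cfg$punct_set)
      cleaned <- cleaned[vapply(cleaned, function(l) l$N_L >= 1L,
                                logical(1))]
      pool <- aggregate_candidates(cleaned, cat)
      zero_hit_items <- unique(unlist(
        lapply(lists, function(l) {
          if (!length(intersect(unique(l$items), seed_set))) l$items
          else character(0)
        }), use.names = FALSE))
      if (is.null(models[[cat]])) {
        pats <- select_top_patterns(
          mine_patterns(sstore, seeds, cat, cfg$language),
          cfg$m_patterns)
        pos_terms <- seeds$entries[[cat]]
        negs <- zero_hit_items
        if (!length(negs)) {
          stop("no zero-hit lists to sample negatives from (category ",
               cat, ")", call. = FALSE)
        }
        n_neg <- min(length(negs), length(pos_terms))
        neg_terms <- with_seed(stage("nbneg"), sample(negs, n_neg))
        fz <- function(tm) {
          featurize(tm, fetch_snippets(sstore, tm), pats, cfg$language)
        }
        nbm <- nb_train(t(vapply(pos_terms, fz, integer(nrow(pats)))),
                        t(vapply(neg_terms, fz, integer(nrow(pats)))),
                        alpha = cfg$alpha,
                        feature_names = paste(pats$side, pats$tokens))
        affix_feats <- extract_affix_features(seeds, cat, cfg$language,
                                              cfg$m_affixes)
        affix_model <- train_affix_model(seeds, cat, affix_feats, negs,
                                         alpha = cfg$alpha,
                                         rng_seed = stage("affixneg"))
        models[[cat]] <- list(patterns = pats, nb = nbm,
                              affix_feats = affix_feats,
                              affix_model = affix_model)
      }
      mdl <- models[[cat]]
      new_pool <- pool_subset(pool, setdiff(names(pool$terms), seed_set))
      n_candidates <- length(new_pool$terms)
      if (cfg$system == "baseline") {
        res <- classify_candidates(new_pool, sstore, mdl$patterns, mdl$nb,
                                   cfg$nb_threshold, cfg$language)
        accepted <- res$accepted
        removed_now <- res$rejected
        n_wholesale <- 0L
        n_deferred <- n_candidates
      } else {
        ql <- select_quality_lists(cleaned, params, cfg$gate)
        wholesale <- unique(unlist(lapply(ql, `[[`, "items"),
                                   use.names = FALSE))
        wholesale <- intersect(wholesale, names(new_pool$terms))
        scored <- score_entities(new_pool, cleaned, params,
                                 mdl$affix_model, mdl$affix_feats,
                                 cfg$language)
        gate <- combined_gate(scored, wholesale, cfg$gate)
        def_pool <- pool_subset(new_pool, gate$deferred)
        snip <- classify_candidates(def_pool, sstore, mdl$patterns,
                                    mdl$nb, cfg$nb_threshold,
                                    cfg$language)
        accepted <- union(gate$accepted, snip$accepted)
        removed_now <- union(gate$deleted, snip$rejected)
        n_wholesale <- length(wholesale)
        n_deferred <- length(gate$deferred)
      }
      removed[[cat]] <- union(removed[[cat]], removed_now)
      new_terms <- setdiff(accepted, seed_set)
      seeds <- merge_dictionaries(
        seeds, seed_dictionary(cfg$language,
                               stats::setNames(list(accepted), cat)))
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = iter, category = cat, system = cfg$system,
        n_pages = length(pages), n_lists = length(lists),
        n_selected = length(selected), n_candidates = n_candidates,
        n_wholesale = n_wholesale, n_deferred = n_deferred,
        n_accepted_new = length(new_terms),
        n_removed = length(removed_now),
        dictionary_size = length(seeds$entries[[cat]]),
        stringsAsFactors = FALSE)
      if (length(new_terms)) added_any <- TRUE
    }
    if (!added_any) break
  }
  list(dictionary = seeds, seeds = cfg$seeds, removed = removed,
       report = do.call(rbind, rows), models = models)
}

#' Evaluate a pipeline run against a reference corpus
#'
#' Builds per-category truth oracles from the label file, then computes
#' the full report (P, the three recalls, F-measures, Err over the
#' removed candidates) for each expanded category.
#'
#' @param result value of [run_pipeline()].
#' @param ref a `reference_corpus` (or path to a reference TSV).
#' @param labels data.frame from [load_labels()] (or its path).
#' @param head_lexicon,modifier_lexicon lexicons for the default head
#'   extractor (character vectors or file paths).
#' @param language `"en"` or `"zh"`.
#' @param n_sample sample size for P and Err.
#' @param rng_seed sampling seed.
#' @return named list of `evaluation_report` objects, one per category.
#' @export
evaluate_run <- function(result, ref, labels, head_lexicon = character(0),
                         modifier_lexicon = character(0),
                         language = c("en", "zh"), n_sample = 1000L,
                         rng_seed = 1L) {
  language <- check_language(language)
  if (is.character(ref)) ref <- load_reference(ref, language)
  if (is.character(labels)) labels <- load_labels(labels)
  if (length(head_lexicon) == 1L && file.exists(head_lexicon)) {
    head_lexicon <- readLines(head_lexicon, encoding = "UTF-8")
  }
  if (length(modifier_lexicon) == 1L && file.exists(modifier_lexicon)) {
    modifier_lexicon <- readLines(modifier_lexicon, encoding = "UTF-8")
  }
  hx <- function(term) {
    default_head_extractor(term, language, modifier_lexicon, head_lexicon)
  }
  out <- list()
  for (cat in names(result$removed)) {
    truth <- labels$surface[labels$is_term == 1L & labels$category == cat]
    dict <- result$dictionary$entries[[cat]]
    out[[cat]] <- evaluation_report(
      dict, ref, truth_oracle = truth, removed = result$removed[[cat]],
      head_extractor = hx, category = cat, n_sample = n_sample,
      rng_seed = derive_seed(rng_seed, paste0("eval-", cat)))
  }
  out
}
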