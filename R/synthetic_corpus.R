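# Synthetic corpus generator: a fully seeded miniature "web" -- HTML
# pages with parallel structures, a snippet store, an encyclopedia dump,
# a reference corpus with synonym/head maps, and exhaustive truth labels
# -- carrying the statistical regularities every pipeline stage assumes:
# category-typical affixes, term columns mixing seeds with unseen true
# terms, distractor columns (dosages, codes, sentence fragments),
# category-specific boundary context patterns, and a rare-term stratum
# that appears on lists but never in snippets.

#' Configuration of the synthetic corpus
#'
#' Defaults define the standard study conditions: 3 categories x 200
#' true terms, 80 of them seeds, 50 pages of 200-item term columns,
#' pattern emission probability 0.9, distractor rate 0.5, 10 snippets
#' per term, and a 20% rare stratum among non-seed terms.
#'
#' @param language `"en"` or `"zh"`.
#' @param n_true_terms true terms per category.
#' @param n_seed_terms of which are seeds.
#' @param rare_fraction fraction of non-seed true terms with zero
#'   snippets (rare on the web).
#' @param variant_fraction fraction of true terms given a surface
#'   variant (registered as the same object in the reference).
#' @param affix_prob probability a head word carries its category's
#'   typical affix.
#' @param n_pages number of HTML pages.
#' @param items_per_list items in each page's term column.
#' @param seed_fraction probability a non-distractor term-column slot
#'   holds a seed (vs an unseen true term).
#' @param distractor_rate probability a term-column slot is replaced by
#'   a distractor; 0 makes every term column pure.
#' @param snippets_per_term snippets stored per term.
#' @param snippet_pattern_emission_prob probability a true term's
#'   snippet carries a category pattern at a context boundary.
#' @param background_emission_prob same for distractor snippets
#'   (category chosen at random).
#' @param rng_seed master seed; identical config + seed regenerate the
#'   corpus byte-identically.
#' @return object of class `corpus_config`.
#' @export
corpus_config <- function(language = c("en", "zh"), n_true_terms = 200L,
                          n_seed_terms = 80L, rare_fraction = 0.2,
                          variant_fraction = 0.15, affix_prob = 0.8,
                          n_pages = 50L, items_per_list = 200L,
                          seed_fraction = 0.6, distractor_rate = 0.5,
                          snippets_per_term = 10L,
                          snippet_pattern_emission_prob = 0.9,
                          background_emission_prob = 0.05,
                          rng_seed = 1L) {
  language <- match.arg(language)
  stopifnot(n_true_terms >= 1L, n_seed_terms >= 2L,
            n_seed_terms < n_true_terms,
            rare_fraction >= 0, rare_fraction <= 1,
            variant_fraction >= 0, variant_fraction <= 1,
            affix_prob >= 0, affix_prob <= 1,
            n_pages >= 1L, items_per_list >= 1L,
            seed_fraction >= 0, seed_fraction <= 1,
            distractor_rate >= 0, distractor_rate <= 1,
            snippets_per_term >= 1L,
            snippet_pattern_emission_prob >= 0,
            snippet_pattern_emission_prob <= 1,
            background_emission_prob >= 0, background_emission_prob <= 1)
  structure(list(
    language = language, n_true_terms = as.integer(n_true_terms),
    n_seed_terms = as.integer(n_seed_terms),
    rare_fraction = rare_fraction, variant_fraction = variant_fraction,
    affix_prob = affix_prob, n_pages = as.integer(n_pages),
    items_per_list = as.integer(items_per_list),
    seed_fraction = seed_fraction, distractor_rate = distractor_rate,
    snippets_per_term = as.integer(snippets_per_term),
    snippet_pattern_emission_prob = snippet_pattern_emission_prob,
    background_emission_prob = background_emission_prob,
    rng_seed = as.integer(rng_seed)), class = "corpus_config")
}

#' Category-typical affix pools of the generator
#' @param language `"en"` or `"zh"`.
#' @return named list mapping categories to suffix strings.
#' @export
category_affix_pools <- function(language = c("en", "zh")) {
  language <- match.arg(language)
  if (language == "en") {
    list(PROBLEM = c("itis", "osis", "oma"),
         MEDICATION = c("cillin", "mycin", "olol"),
         TEST = c("scopy", "gram", "metry"))
  } else {
    list(PROBLEM = c("炎", "症", "瘤"),
         MEDICATION = c("胶囊", "片", "素"),
         TEST = c("镜", "图", "检"))
  }
}

#' Category context-pattern pools of the generator
#'
#' The boundary n-grams the snippet generator plants: instruction and
#' side-effect contexts for medications, symptom/treatment contexts for
#' problems, result/range contexts for tests.
#' @param language `"en"` or `"zh"`.
#' @return named list of data.frames with `tokens` and `side`.
#' @export
category_pattern_pools <- function(language = c("en", "zh")) {
  language <- match.arg(language)
  mk <- function(follows, precedes) {
    data.frame(tokens = c(follows, precedes),
               side = rep(c("follows", "precedes"),
                          c(length(follows), length(precedes))),
               stringsAsFactors = FALSE)
  }
  if (language == "en") {
    list(
      PROBLEM = mk(c("symptoms", "treatment options", "causes and risk"),
                   c("diagnosed with", "suffering from")),
      MEDICATION = mk(c("side effects", "dosage information",
                        "instruction leaflet"),
                      c("commonly prescribed", "taking the drug")),
      TEST = mk(c("normal range", "results explained", "procedure steps"),
                c("ordered a", "schedule your")))
  } else {
    list(
      PROBLEM = mk(c("症状", "治疗方法", "病因"), c("诊断为", "患有")),
      MEDICATION = mk(c("说明书", "副作用", "功效"), c("常用药", "服用")),
      TEST = mk(c("正常值", "结果分析", "临床意义"), c("化验", "检测")))
  }
}

#' @noRd
neutral_filler_pool <- function(language) {
  if (language == "en") {
    c("more", "details", "page", "online", "overview", "reference",
      "article", "general", "related", "resource", "archive", "portal")
  } else {
    strsplit("的大全最新相关介绍内容资料网页专题", "")[[1]]
  }
}

#' @noRd
rand_words <- function(n, min_syll = 2L, max_syll = 3L) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z", "dr", "tr", "pl")
  vows <- c("a", "e", "i", "o", "u")
  vapply(seq_len(n), function(i) {
    k <- sample(min_syll:max_syll, 1)
    paste0(paste0(sample(cons, k, replace = TRUE),
                  sample(vows, k, replace = TRUE)), collapse = "")
  }, character(1))
}

#' @noRd
rand_zh_chars <- function(n) {
  pool <- strsplit(paste0("安宝川丹尔芬冈禾吉克兰美宁平奇仁思汀维西",
                          "雅泽贝洛肺胃肝肾脑心血骨肌"), "")[[1]]
  vapply(seq_len(n), function(i) {
    paste0(sample(pool, sample(1:2, 1), replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate the synthetic vocabulary
#'
#' True terms are modifier+head compositions whose heads carry
#' category-typical affixes with probability `affix_prob`; a fraction of
#' terms get a registered surface variant (same object); distractors are
#' dosage strings, bracketed codes, long sentence fragments, and short
#' fragments containing forbidden-POS words. Deterministic under the
#' config seed.
#'
#' @param cfg a [corpus_config()].
#' @return list with `terms` (data.frame: surface, category, object_id,
#'   head, is_seed, is_rare, is_variant), `distractors` (data.frame:
#'   surface, kind), `modifier_lexicon`, `head_lexicon`.
#' @export
gen_vocabulary <- function(cfg) {
  stopifnot(inherits(cfg, "corpus_config"))
  with_seed(derive_seed(cfg$rng_seed, "vocabulary"), {
    lang <- cfg$language
    affixes <- category_affix_pools(lang)
    if (lang == "en") {
      modifiers <- unique(rand_words(40, 2, 2))[1:24]
      base_words <- unique(rand_words(cfg$n_true_terms * 6L, 2, 3))
    } else {
      modifiers <- unique(rand_zh_chars(60))[1:24]
      base_words <- unique(rand_zh_chars(cfg$n_true_terms * 8L))
    }
    base_i <- 0L
    next_base <- function() {
      base_i <<- base_i + 1L
      if (base_i > length(base_words)) stop("base word pool exhausted")
      base_words[[base_i]]
    }
    seen <- new.env(parent = emptyenv())
    rows <- list()
    heads_all <- character(0)
    for (cat in CATEGORIES) {
      made <- 0L
      while (made < cfg$n_true_terms) {
        head <- next_base()
        if (stats::runif(1) < cfg$affix_prob) {
          head <- paste0(head, sample(affixes[[cat]], 1))
        }
        n_mod <- sample(0:2, 1, prob = c(0.3, 0.55, 0.15))
        mods <- if (n_mod) sample(modifiers, n_mod) else character(0)
        surface <- if (lang == "en") {
          paste(c(mods, head), collapse = " ")
        } else {
          paste0(paste0(mods, collapse = ""), head)
        }
        if (!is.null(seen[[surface]])) next
        seen[[surface]] <- TRUE
        made <- made + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          surface = surface, category = cat,
          object_id = sprintf("%s-%04d", substr(cat, 1, 1), made),
          head = head, n_mod = n_mod, stringsAsFactors = FALSE)
        heads_all <- c(heads_all, head)
      }
    }
    terms <- do.call(rbind, rows)
    terms$surface <- normalize_term(terms$surface, lang)
    terms$head <- normalize_term(terms$head, lang)
    # seed / rare strata, per category
    terms$is_seed <- FALSE
    terms$is_rare <- FALSE
    for (cat in CATEGORIES) {
      idx <- which(terms$category == cat)
      seed_idx <- sample(idx, cfg$n_seed_terms)
      terms$is_seed[seed_idx] <- TRUE
      nonseed <- setdiff(idx, seed_idx)
      n_rare <- round(cfg$rare_fraction * length(nonseed))
      if (n_rare) terms$is_rare[sample(nonseed, n_rare)] <- TRUE
    }
    terms$is_variant <- FALSE
    # surface variants: shortened modifier, same object
    multi <- which(terms$n_mod > 0 & !terms$is_variant)
    n_var <- round(cfg$variant_fraction * nrow(terms))
    var_rows <- list()
    for (i in utils::head(sample(multi), n_var)) {
      surf <- terms$surface[[i]]
      variant <- if (lang == "en") {
        toks <- strsplit(surf, " ", fixed = TRUE)[[1]]
        paste(c(substr(toks[[1]], 1, 3), toks[-1]), collapse = " ")
      } else {
        substring(surf, 2)
      }
      variant <- normalize_term(variant, lang)
      if (!nzchar(variant) || !is.null(seen[[variant]])) next
      seen[[variant]] <- TRUE
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        surface = variant, category = terms$category[[i]],
        object_id = terms$object_id[[i]], head = terms$head[[i]],
        n_mod = terms$n_mod[[i]], is_seed = FALSE, is_rare = TRUE,
        is_variant = TRUE, stringsAsFactors = FALSE)
    }
    if (length(var_rows)) terms <- rbind(terms, do.call(rbind, var_rows))
    rownames(terms) <- NULL
    # distractors
    if (lang == "en") {
      doses <- paste0(sample(c(5, 10, 25, 50, 100, 250, 500), 60,
                             replace = TRUE), " mg, ",
                      sample(c("once", "twice", "three times"), 60,
                             replace = TRUE), " daily dose ",
                      seq_len(60))
      codes <- sprintf("[%s%02d.%02d]",
                       sample(LETTERS, 45, replace = TRUE),
                       sample(0:99, 45, replace = TRUE),
                       sample(0:99, 45, replace = TRUE))
      frag_words <- c("take", "with", "food", "and", "plenty", "water",
                      "before", "meals", "every", "single", "morning")
      longfrag <- vapply(seq_len(30), function(i) {
        paste(c(sample(frag_words, 6, replace = TRUE),
                sample(c("of", "his", "it"), 1),
                sample(frag_words, 1)), collapse = " ")
      }, character(1))
      shortfrag <- c("how to use", "what it treats", "when to take",
                     "why choose us", "take with his", "where to buy",
                     "who should avoid", "how it works", "what you need",
                     "which one works", "why it matters", "ask your doctor of",
                     "how to store", "what to expect", "when it expires")
    } else {
      doses <- paste0(sample(c(5, 10, 25, 50, 100, 250), 60, replace = TRUE),
                      "毫克，每日", sample(1:3, 60, replace = TRUE), "次",
                      seq_len(60))
      codes <- sprintf("【%s%02d.%02d】",
                       sample(LETTERS, 45, replace = TRUE),
                       sample(0:99, 45, replace = TRUE),
                       sample(0:99, 45, replace = TRUE))
      longfrag <- vapply(seq_len(30), function(i) {
        paste0(paste0(sample(neutral_filler_pool("zh"), 14, replace = TRUE),
                      collapse = ""), "他说明")
      }, character(1))
      shortfrag <- c("怎么用它", "他怎么说", "如何服用", "怎么保存它",
                     "他如何选择", "如何购买它", "怎么办它", "他怎么用",
                     "如何检查它", "怎么预防他", "它如何起效", "他如何治",
                     "如何用他", "怎么选它", "它怎么治")
    }
    distractors <- data.frame(
      surface = normalize_term(c(doses, codes, longfrag, shortfrag), lang),
      kind = rep(c("dose", "code", "longfrag", "shortfrag"),
                 c(length(doses), length(codes), length(longfrag),
                   length(shortfrag))),
      stringsAsFactors = FALSE)
    distractors <- distractors[!duplicated(distractors$surface), ,
                               drop = FALSE]
    distractors <-
      distractors[!distractors$surface %in% terms$surface, , drop = FALSE]
    rownames(distractors) <- NULL
    list(terms = terms, distractors = distractors,
         modifier_lexicon = normalize_term(modifiers, lang),
         head_lexicon = sort(unique(normalize_term(heads_all, lang)),
                             method = "radix"))
  })
}

#' @noRd
vocab_seeds <- function(vocab) {
  t <- vocab$terms
  entries <- lapply(stats::setNames(CATEGORIES, CATEGORIES), function(cat) {
    t$surface[t$category == cat & t$is_seed]
  })
  entries
}

#' Generate the HTML page store
#'
#' Pages cycle over the three categories. Each page holds one term
#' column -- a parallel structure whose slots are, independently, a
#' distractor with probability `distractor_rate`, else a seed with
#' probability `seed_fraction`, else an unseen true term -- and sibling
#' distractor columns (dosages, codes) under distinct tag-class paths.
#' Each page's issuing query is a pair of seeds of its category. Files
#' and a JSONL manifest are written under `dir`.
#'
#' @param cfg a [corpus_config()].
#' @param vocab result of [gen_vocabulary()].
#' @param dir output directory (created if needed).
#' @return list with `manifest_path` and `truth` (data.frame: page_id,
#'   list role, item, category), invisibly usable as ground truth.
#' @export
gen_pages <- function(cfg, vocab, dir) {
  stopifnot(inherits(cfg, "corpus_config"))
  dir.create(file.path(dir, "pages"), recursive = TRUE,
             showWarnings = FALSE)
  with_seed(derive_seed(cfg$rng_seed, "pages"), {
    t <- vocab$terms
    d <- vocab$distractors
    manifest <- list()
    truth <- list()
    for (p in seq_len(cfg$n_pages)) {
      cat_p <- CATEGORIES[((p - 1L) %% 3L) + 1L]
      seeds_p <- t$surface[t$category == cat_p & t$is_seed]
      nonseeds_p <- t$surface[t$category == cat_p & !t$is_seed &
                                !t$is_variant]
      query <- sample(seeds_p, 2L)
      n_it <- cfg$items_per_list
      u <- stats::runif(n_it)
      items <- character(n_it)
      for (i in seq_len(n_it)) {
        items[[i]] <- if (u[[i]] < cfg$distractor_rate) {
          sample(d$surface, 1)
        } else if (stats::runif(1) < cfg$seed_fraction) {
          sample(seeds_p, 1)
        } else {
          sample(nonseeds_p, 1)
        }
      }
      n_dose <- 30L
      dose_col <- sample(d$surface[d$kind == "dose"], n_dose, replace = TRUE)
      code_col <- sample(d$surface[d$kind == "code"], n_dose, replace = TRUE)
      li <- function(cls, x) {
        sprintf('      <div class="%s"><span>%s</span></div>',
                cls, html_escape(x))
      }
      html <- c(
        "<html>",
        sprintf("  <head><title>%s</title></head>",
                html_escape(paste(query, collapse = " "))),
        "  <body>",
        '    <div class="listing main">',
        li("cell name", items),
        li("cell dose", dose_col),
        li("cell code", code_col),
        "    </div>",
        "  </body>",
        "</html>")
      page_id <- sprintf("p%03d", p)
      rel <- file.path("pages", paste0(page_id, ".html"))
      writeLines(html, file.path(dir, rel), useBytes = TRUE)
      manifest[[p]] <- list(page_id = page_id, path = rel,
                            query = as.list(query))
      truth[[p]] <- data.frame(
        page_id = page_id, category = cat_p,
        role = c(rep("term", n_it), rep("distractor", 2L * n_dose)),
        item = c(items, dose_col, code_col), stringsAsFactors = FALSE)
    }
    manifest_path <- file.path(dir, "manifest.jsonl")
    write_jsonl(manifest, manifest_path)
    list(manifest_path = manifest_path, truth = do.call(rbind, truth))
  })
}

#' Generate the snippet store
#'
#' Seeds and non-rare true terms get `snippets_per_term` snippets; each
#' carries a category pattern at a context boundary with probability
#' `snippet_pattern_emission_prob` (otherwise the term sits mid-context
#' and yields no pattern). Distractors emit patterns of a random
#' category at the background rate. Rare terms and surface variants get
#' no snippets at all.
#'
#' @param cfg a [corpus_config()].
#' @param vocab result of [gen_vocabulary()].
#' @param path output JSONL path.
#' @return the path, invisibly.
#' @export
gen_snippets <- function(cfg, vocab, path) {
  stopifnot(inherits(cfg, "corpus_config"))
  with_seed(derive_seed(cfg$rng_seed, "snippets"), {
    lang <- cfg$language
    pools <- category_pattern_pools(lang)
    filler <- neutral_filler_pool(lang)
    glue <- function(...) {
      parts <- c(...)
      if (lang == "en") paste(parts, collapse = " ") else
        paste(parts, collapse = "")
    }
    some_filler <- function(k) {
      paste(sample(filler, k, replace = TRUE),
            collapse = if (lang == "en") " " else "")
    }
    mk_context <- function(term, category, emit_prob) {
      if (stats::runif(1) < emit_prob) {
        pool <- pools[[category]]
        j <- sample(nrow(pool), 1)
        if (pool$side[[j]] == "follows") {
          glue(term, pool$tokens[[j]], some_filler(2))
        } else {
          glue(some_filler(2), pool$tokens[[j]], term)
        }
      } else {
        glue(some_filler(2), term, some_filler(2))
      }
    }
    recs <- list()
    add_term <- function(term, category, emit_prob) {
      for (r in seq_len(cfg$snippets_per_term)) {
        recs[[length(recs) + 1L]] <<- list(
          term = term, rank = r,
          title = glue(term, if (lang == "en") "overview" else "介绍"),
          url = paste0("http://example.test/", length(recs) + 1L),
          context = mk_context(term, category, emit_prob))
      }
    }
    t <- vocab$terms
    live <- t[!t$is_rare & !t$is_variant, , drop = FALSE]
    for (i in seq_len(nrow(live))) {
      add_term(live$surface[[i]], live$category[[i]],
               cfg$snippet_pattern_emission_prob)
    }
    d <- vocab$distractors
    for (i in seq_len(nrow(d))) {
      add_term(d$surface[[i]], sample(CATEGORIES, 1),
               cfg$background_emission_prob)
    }
    write_jsonl(recs, path)
    invisible(path)
  })
}

#' Default seed tags / page rules matching the generated encyclopedia
#' @param language `"en"` or `"zh"`.
#' @return named list (tags) / list of [page_rule()] objects.
#' @export
default_seed_tags <- function(language = c("en", "zh")) {
  language <- match.arg(language)
  if (language == "en") {
    list(PROBLEM = "disease", MEDICATION = "drug", TEST = "diagnostic")
  } else {
    list(PROBLEM = "疾病", MEDICATION = "药物", TEST = "检查")
  }
}

#' @rdname default_seed_tags
#' @export
default_page_rules <- function(language = c("en", "zh")) {
  language <- match.arg(language)
  kw <- if (language == "en") {
    list(PROBLEM = "symptoms", MEDICATION = "side effects",
         TEST = "normal range")
  } else {
    list(PROBLEM = "症状", MEDICATION = "不良反应", TEST = "正常值")
  }
  lapply(CATEGORIES, function(cat) page_rule(cat, kw[[cat]]))
}

#' Generate the encyclopedia dump
#'
#' Entries cover the seeds and half of the non-rare unseen terms. Each
#' carries its category tag plus an occasional secondary tag, related
#' links to same-category entries, and -- with probability 0.9 -- the
#' category keyword its page rule requires (keyword-free entries model
#' pages too thin to trust).
#'
#' @param cfg a [corpus_config()].
#' @param vocab result of [gen_vocabulary()].
#' @param path output JSONL path.
#' @return the path, invisibly.
#' @export
gen_encyclopedia <- function(cfg, vocab, path) {
  stopifnot(inherits(cfg, "corpus_config"))
  with_seed(derive_seed(cfg$rng_seed, "encyclopedia"), {
    lang <- cfg$language
    tags <- default_seed_tags(lang)
    kw <- if (lang == "en") {
      list(PROBLEM = "symptoms", MEDICATION = "side effects",
           TEST = "normal range")
    } else {
      list(PROBLEM = "症状", MEDICATION = "不良反应", TEST = "正常值")
    }
    t <- vocab$terms
    pick <- t$is_seed
    nonseed <- which(!t$is_seed & !t$is_rare & !t$is_variant)
    pick[sample(nonseed, length(nonseed) %/% 2L)] <- TRUE
    ent <- t[pick, , drop = FALSE]
    recs <- list()
    for (i in seq_len(nrow(ent))) {
      cat_i <- ent$category[[i]]
      has_kw <- stats::runif(1) < 0.9
      content <- if (lang == "en") {
        paste(ent$surface[[i]], "is described here.",
              if (has_kw) paste("Information on", kw[[cat_i]],
                                "is included.") else "")
      } else {
        paste0(ent$surface[[i]], "的介绍。",
               if (has_kw) paste0("包含", kw[[cat_i]], "信息。") else "")
      }
      same <- setdiff(ent$surface[ent$category == cat_i], ent$surface[[i]])
      related <- sample(same, min(2L, length(same)))
      entry_tags <- c(tags[[cat_i]],
                      if (stats::runif(1) < 0.3) paste0(tags[[cat_i]], "2"))
      recs[[length(recs) + 1L]] <- list(
        title = ent$surface[[i]], content = content,
        tags = as.list(entry_tags), related = as.list(related))
    }
    write_jsonl(recs, path)
    invisible(path)
  })
}

#' Generate the complete synthetic corpus on disk
#'
#' Writes everything the pipeline consumes, in exactly the formats the
#' upstream modules read: `pages/` + `manifest.jsonl` (page store),
#' `snippets.jsonl` (snippet store), `encyclopedia.jsonl`, `seeds.tsv`,
#' `reference.tsv` (surface/category/object/head), `labels.tsv`
#' (exhaustive truth labels: every generated surface exactly once), and
#' the modifier/head lexicons used by the default head extractor.
#'
#' @param cfg a [corpus_config()].
#' @param dir output directory.
#' @return list with `cfg`, `vocab`, `dir`, the store paths, and
#'   `page_truth` (ground-truth list membership).
#' @export
gen_corpus <- function(cfg, dir) {
  stopifnot(inherits(cfg, "corpus_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vocab <- gen_vocabulary(cfg)
  pages <- gen_pages(cfg, vocab, dir)
  snip_path <- file.path(dir, "snippets.jsonl")
  gen_snippets(cfg, vocab, snip_path)
  enc_path <- file.path(dir, "encyclopedia.jsonl")
  gen_encyclopedia(cfg, vocab, enc_path)
  seeds <- seed_dictionary(cfg$language, vocab_seeds(vocab))
  seeds_path <- file.path(dir, "seeds.tsv")
  save_dictionary(seeds, seeds_path)
  t <- vocab$terms
  ref_path <- file.path(dir, "reference.tsv")
  utils::write.table(
    data.frame(surface = t$surface, category = t$category,
               object_id = t$object_id, head = t$head),
    ref_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE, fileEncoding = "UTF-8")
  labels <- rbind(
    data.frame(surface = t$surface, category = t$category, is_term = 1L,
               stringsAsFactors = FALSE),
    data.frame(surface = vocab$distractors$surface, category = "NONE",
               is_term = 0L, stringsAsFactors = FALSE))
  labels_path <- file.path(dir, "labels.tsv")
  utils::write.table(labels, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  writeLines(vocab$head_lexicon, file.path(dir, "head_lexicon.txt"),
             useBytes = TRUE)
  writeLines(vocab$modifier_lexicon, file.path(dir, "modifier_lexicon.txt"),
             useBytes = TRUE)
  list(cfg = cfg, vocab = vocab, dir = dir,
       manifest_path = pages$manifest_path,
       snippets_path = snip_path, encyclopedia_path = enc_path,
       seeds_path = seeds_path, reference_path = ref_path,
       labels_path = labels_path, page_truth = pages$truth)
}

#' Load the truth labels written by [gen_corpus()]
#' @param path the `labels.tsv` path.
#' @return data.frame `surface`, `category`, `is_term`.
#' @export
load_labels <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    col.names = c("surface", "category", "is_term"),
                    colClasses = c("character", "character", "integer"))
}
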