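test_that("length fitness is 1 up to l_p, calibrated at 2*l_p, then decays", {
  en <- length_params("en")
  zh <- length_params("zh")
  expect_identical(length_fitness(2, en), 1)
  expect_identical(length_fitness(5, zh), 1)
  expect_equal(length_fitness(4, en), 0.1, tolerance = 1e-12)
  expect_equal(length_fitness(10, zh), 0.1, tolerance = 1e-12)
  # continuity at l_p and strict decay beyond; never zero
  ls <- seq(1, 20, by = 0.25)
  f <- length_fitness(ls, en)
  expect_true(all(f > 0 & f <= 1))
  expect_true(all(f[ls <= 2] == 1))
  beyond <- f[ls > 2]
  expect_true(all(diff(beyond) < 0))
  expect_equal(length_fitness(2 + 1e-12, en), 1, tolerance = 1e-9)
})

test_that("list quality is hit-count dominant with logarithmic size damping", {
  params <- length_params("en")
  l <- mk_list(rep("a b", 100), hits = paste0("s", 1:12))
  expect_equal(list_score(l, params), 12 / log2(102), tolerance = 1e-12)
  l0 <- mk_list(rep("a b", 100))
  expect_identical(list_score(l0, params), 0)
  l2 <- l
  l2$H_L <- 24L
  expect_equal(list_score(l2, params), 2 * list_score(l, params),
               tolerance = 1e-12)
  bigger <- l
  bigger$N_L <- 400L
  expect_lt(list_score(bigger, params), list_score(l, params))
})

test_that("quality-list selection matches a sort+filter oracle", {
  params <- length_params("en")
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    lists <- lapply(seq_len(n), function(i) {
      mk_list(rep("a", sample(2:300, 1)),
              list_id = sprintf("L%03d", i),
              hits = paste0("s", seq_len(sample(0:30, 1))))
    })
    cfg <- gate_config(top_lists = sample(3:20, 1),
                       min_list_entities = sample(c(0, 50, 100), 1))
    got <- select_quality_lists(lists, params, cfg)
    sq <- vapply(lists, list_score, numeric(1), params = params)
    ord <- order(-sq, -vapply(lists, `[[`, numeric(1), "H_L"),
                 vapply(lists, `[[`, character(1), "list_id"),
                 method = "radix")
    brute <- lists[utils::head(ord, cfg$top_lists)]
    brute <- brute[vapply(brute, function(l) l$N_L > cfg$min_list_entities,
                          logical(1))]
    expect_identical(vapply(got, `[[`, character(1), "list_id"),
                     vapply(brute, `[[`, character(1), "list_id"))
    # invariance to input order
    got2 <- select_quality_lists(rev(lists), params, cfg)
    expect_identical(vapply(got2, `[[`, character(1), "list_id"),
                     vapply(got, `[[`, character(1), "list_id"))
  }
})

test_that("POS gate discards pronouns, particles, question words", {
  expect_identical(pos_gate(c("NN", "NN")), 1L)
  expect_identical(pos_gate(c("PRP", "NN")), 0L)
  expect_identical(pos_gate(character(0)), 1L)
  expect_identical(pos_gate(toy_pos_tagger(c("chest", "pain"))), 1L)
  expect_identical(pos_gate(toy_pos_tagger(c("his", "pain"))), 0L)
  expect_identical(pos_gate(toy_pos_tagger(c("how", "to", "use"))), 0L)
  expect_identical(pos_gate(toy_pos_tagger(c("shortness", "of", "breath"))),
                   0L)
})

test_that("affix extraction ranks frequent affixes and bounds lengths", {
  seeds <- seed_dictionary("en", list(TEST = c(
    "gastroscopy", "colonoscopy", "bronchoscopy", "arthroscopy",
    "cystoscopy", "angiogram", "myelogram")))
  feats <- extract_affix_features(seeds, "TEST", "en", m = 20)
  expect_lte(nrow(feats), 20L)
  expect_true(all(nchar(feats$affix) <= 5))
  expect_true("scopy" %in% feats$affix[feats$position == "suffix"])
  top_suffix_y <- feats[feats$affix == "y" & feats$position == "suffix", ]
  expect_identical(top_suffix_y$freq, 5L)

  short <- seed_dictionary("zh", list(PROBLEM = c("炎", "瘤")))
  fs <- extract_affix_features(short, "PROBLEM", "zh", m = 50)
  expect_true(all(nchar(fs$affix) <= 1))
  big_m <- extract_affix_features(short, "PROBLEM", "zh", m = 1000)
  expect_identical(nrow(big_m), nrow(fs))
})

test_that("affix featurization implements the starts/ends-with contract", {
  feats <- affix_feature_set(
    data.frame(affix = c("scopy", "copy", "ia"), position = "suffix"),
    "en")
  expect_identical(affix_featurize("gastroscopy", feats), c(1L, 1L, 0L))
  expect_identical(affix_featurize("ia", feats), c(0L, 0L, 1L))
  # term shorter than the affix
  expect_identical(affix_featurize("py", feats)[1:2], c(0L, 0L))

  set.seed(29)
  for (rep in 1:40) {
    term <- paste(sample(letters, sample(2:10, 1), TRUE), collapse = "")
    fs <- affix_feature_set(data.frame(
      affix = replicate(4, paste(sample(letters, sample(1:5, 1), TRUE),
                                 collapse = "")),
      position = sample(c("prefix", "suffix"), 4, TRUE)), "en")
    got <- affix_featurize(term, fs)
    brute <- vapply(seq_len(4), function(j) {
      if (fs$position[j] == "prefix") as.integer(startsWith(term, fs$affix[j]))
      else as.integer(endsWith(term, fs$affix[j]))
    }, integer(1))
    expect_identical(got, brute)
  }
})

test_that("affix confidence is a deterministic posterior with prior fallback", {
  feats <- affix_feature_set(
    data.frame(affix = c("scopy", "itis"), position = "suffix"), "en")
  pos <- t(vapply(c("gastroscopy", "colonoscopy", "cystoscopy"),
                  affix_featurize, integer(2), feats = feats))
  neg <- t(vapply(c("take daily", "see below", "misc"),
                  affix_featurize, integer(2), feats = feats))
  m <- nb_train(pos, neg)
  a1 <- affix_confidence("arthroscopy", m, feats)
  expect_gt(a1, 0.5)
  expect_identical(a1, affix_confidence("arthroscopy", m, feats))
  u <- structure(list(feature_names = c("a", "b"), prior_pos = 0.6,
                      prior_neg = 0.4, cond_pos = c(0.3, 0.3),
                      cond_neg = c(0.3, 0.3), alpha = 1),
                 class = "naive_bayes_model")
  expect_equal(affix_confidence("anything", u, feats), 0.6,
               tolerance = 1e-12)
})

test_that("entity score multiplies gates into the list-quality mass", {
  es <- entity_score("t", c(1.8, 0.2), f_val = 1, g_val = 1L, A_val = 0.8)
  expect_equal(es$S_E, 0.8 * 2.0, tolerance = 1e-12)
  expect_identical(es$M, 2L)
  gz <- entity_score("t", c(1.8, 0.2), f_val = 1, g_val = 0L, A_val = 0.8)
  expect_identical(gz$S_E, 0)
  # monotone in M and symmetric under permutation of lists
  one <- entity_score("t", 0.3, 1, 1L, 0.5)
  two <- entity_score("t", c(0.3, 0.1), 1, 1L, 0.5)
  expect_gte(two$S_E, one$S_E)
  set.seed(4)
  for (rep in 1:20) {
    sq <- stats::runif(sample(1:6, 1), 0, 3)
    e1 <- entity_score("t", sq, 0.7, 1L, 0.4)
    e2 <- entity_score("t", sq[sample(seq_along(sq))], 0.7, 1L, 0.4)
    expect_equal(e1$S_E, e2$S_E, tolerance = 1e-12)
  }
  mx <- entity_score("t", c(1.8, 0.2), 1, 1L, 1, agg = "max")
  expect_equal(mx$S_E, 1.8, tolerance = 1e-12)
})

test_that("combined gate partitions and is monotone in the delete threshold", {
  scored <- data.frame(term = paste0("t", 1:10), M = 1L, f = 1, g = 1L,
                       A = 0.5, sum_Sq = 1,
                       S_E = c(0.05, 0.08, 0.2, 0.5, 0.9, 1.4, 2, 3, 4, 5),
                       stringsAsFactors = FALSE)
  g <- combined_gate(scored, wholesale_terms = character(0),
                     cfg = gate_config(accept_top_entities = 2,
                                       delete_below = 0.1))
  expect_setequal(g$accepted, c("t10", "t9"))
  expect_setequal(g$deleted, c("t1", "t2"))
  expect_setequal(c(g$accepted, g$deleted, g$deferred), scored$term)
  expect_length(intersect(g$deferred, g$accepted), 0L)

  g0 <- combined_gate(scored, character(0),
                      gate_config(delete_below = 0))
  expect_length(g0$deleted, 0L)

  # raising delete_below never grows accepted+deferred
  prev <- Inf
  for (thr in c(0, 0.1, 0.6, 2.5, 10)) {
    gt <- combined_gate(scored, c("w1"),
                        gate_config(delete_below = thr))
    n_live <- length(gt$accepted) + length(gt$deferred)
    expect_lte(n_live, prev)
    prev <- n_live
    expect_true("w1" %in% gt$accepted)
  }
})
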