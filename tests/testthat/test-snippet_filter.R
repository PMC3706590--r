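test_that("patterns come only from context boundaries adjacent to the term", {
  snips <- mk_snips("aspirin side effects include nausea")
  pats <- extract_patterns(snips, "aspirin", "en")
  expect_true(all(pats$side == "follows"))
  expect_setequal(pats$tokens,
                  c("side", "side effects", "side effects include",
                    "side effects include nausea"))

  expect_identical(nrow(extract_patterns(mk_snips("take aspirin daily"),
                                         "aspirin", "en")), 0L)

  zh <- extract_patterns(mk_snips("阿司匹林说明书"), "阿司匹林", "zh")
  expect_setequal(zh$tokens, c("说", "说 明", "说 明 书"))
  expect_true(all(zh$side == "follows"))

  pre <- extract_patterns(mk_snips("doctors prescribed aspirin"),
                          "aspirin", "en")
  expect_true(all(pre$side == "precedes"))
  expect_true("doctors prescribed" %in% pre$tokens)
  expect_true("prescribed" %in% pre$tokens)
})

test_that("pattern score is N_p-monotone, N_o-antimonotone with zero bounds", {
  expect_equal(score_pattern(10, 100, 0), 10 * log(101), tolerance = 1e-12)
  expect_identical(score_pattern(0, 100, 17), 0)
  expect_identical(score_pattern(5, 100, 100), 0)
  expect_error(score_pattern(5, 0, 0), "O")

  set.seed(9)
  for (rep in 1:100) {
    O <- sample(5:200, 1)
    No <- sample(0:O, 1)
    Np <- sample(0:50, 1)
    expect_gte(score_pattern(Np + 1, O, No), score_pattern(Np, O, No))
    if (No < O) {
      expect_lte(score_pattern(Np, O, No + 1), score_pattern(Np, O, No))
    }
  }
})

test_that("top-m selection matches a full-sort oracle with stated tie rule", {
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    df <- data.frame(
      tokens = paste0("tok", sample(999, n)),
      side = sample(c("follows", "precedes"), n, TRUE),
      N_p = sample(1:9, n, TRUE), N_o = 0L,
      score = sample(1:5, n, TRUE) / 2, stringsAsFactors = FALSE)
    m <- sample(1:n, 1)
    got <- select_top_patterns(df, m)
    ord <- df[order(-df$score, -df$N_p, df$tokens, df$side,
                    method = "radix"), ]
    expect_identical(got$tokens, utils::head(ord, m)$tokens)
  }
  all_equal <- data.frame(tokens = c("b", "a", "c"), side = "follows",
                          N_p = 1L, N_o = 0L, score = 1)
  expect_identical(select_top_patterns(all_equal, 2)$tokens, c("a", "b"))
  expect_warning(select_top_patterns(all_equal, 5), "3 patterns")
})

test_that("featurization fires per side/adjacency and zeroes without snippets", {
  pats <- data.frame(tokens = c("side effects", "prescribed"),
                     side = c("follows", "precedes"),
                     stringsAsFactors = FALSE)
  v <- featurize("aspirin", mk_snips(c("aspirin side effects listed")),
                 pats, "en")
  expect_identical(v, c(1L, 0L))
  v2 <- featurize("aspirin", mk_snips("doctor prescribed aspirin"),
                  pats, "en")
  expect_identical(v2, c(0L, 1L))
  expect_identical(featurize("aspirin", mk_snips(character(0)), pats, "en"),
                   c(0L, 0L))
  # wrong side must not fire
  v3 <- featurize("aspirin", mk_snips("side effects aspirin"), pats, "en")
  expect_identical(v3[1], 0L)

  # brute-force scan oracle on random snippet sets
  set.seed(77)
  vocab <- c("use", "dose", "warn", "info", "note")
  for (rep in 1:40) {
    ctxs <- replicate(4, paste(
      c(if (stats::runif(1) < 0.5) "drugx",
        sample(vocab, 3, TRUE),
        if (stats::runif(1) < 0.5) "drugx"), collapse = " "))
    pat <- data.frame(tokens = sample(vocab, 3),
                      side = sample(c("follows", "precedes"), 3, TRUE),
                      stringsAsFactors = FALSE)
    got <- featurize("drugx", mk_snips(ctxs), pat, "en")
    mined <- extract_patterns(mk_snips(ctxs), "drugx", "en")
    brute <- as.integer(paste(pat$side, pat$tokens) %in%
                          paste(mined$side, mined$tokens))
    expect_identical(got, brute)
  }
})

test_that("naive Bayes training matches hand arithmetic and limits", {
  m <- nb_train(matrix(c(1, 1)), matrix(c(0, 0)), alpha = 1)
  expect_equal(unname(m$cond_pos), 3 / 4)
  expect_equal(unname(m$cond_neg), 1 / 4)
  expect_equal(m$prior_pos, 0.5)
  m2 <- nb_train(matrix(c(1, 1)), matrix(c(0, 0)), alpha = 1e-9)
  expect_equal(unname(m2$cond_pos), 1, tolerance = 1e-6)
  expect_error(nb_train(matrix(numeric(0), 0, 1), matrix(0)), "at least one")
})

test_that("posterior equals single-feature Bayes rule by hand", {
  m <- structure(list(feature_names = "f1", prior_pos = 0.5,
                      prior_neg = 0.5, cond_pos = 0.8, cond_neg = 0.2,
                      alpha = 1), class = "naive_bayes_model")
  expect_equal(nb_posterior(m, 1), 0.8, tolerance = 1e-12)
  expect_equal(nb_posterior(m, 0), 0.2, tolerance = 1e-12)
  u <- structure(list(feature_names = "f1", prior_pos = 0.7,
                      prior_neg = 0.3, cond_pos = 0.4, cond_neg = 0.4,
                      alpha = 1), class = "naive_bayes_model")
  expect_equal(nb_posterior(u, 1), 0.7, tolerance = 1e-12)
  expect_error(nb_posterior(m, c(1, 0)), "length")
})

test_that("posterior matches brute-force enumeration on random small models", {
  set.seed(3)
  for (rep in 1:60) {
    d <- sample(1:6, 1)
    pp <- stats::runif(1, 0.1, 0.9)
    cp <- stats::runif(d, 0.05, 0.95)
    cn <- stats::runif(d, 0.05, 0.95)
    m <- structure(list(feature_names = paste0("f", 1:d), prior_pos = pp,
                        prior_neg = 1 - pp, cond_pos = cp, cond_neg = cn,
                        alpha = 1), class = "naive_bayes_model")
    x <- rand_bin(1, d)[1, ]
    joint_pos <- pp * prod(ifelse(x == 1, cp, 1 - cp))
    joint_neg <- (1 - pp) * prod(ifelse(x == 1, cn, 1 - cn))
    expect_equal(nb_posterior(m, x), joint_pos / (joint_pos + joint_neg),
                 tolerance = 1e-12)
  }
})

test_that("trained posteriors agree with an independent naive Bayes fit", {
  skip_if_not_installed("e1071")
  # at alpha = 0 both implementations reduce to the same maximum-
  # likelihood estimates (smoothing conventions differ otherwise), so
  # use data where every feature varies within each class
  set.seed(88)
  d <- 4
  repeat {
    pos <- rand_bin(30, d, 0.7)
    neg <- rand_bin(40, d, 0.3)
    ok <- all(colSums(pos) %in% 1:29) && all(colSums(neg) %in% 1:39)
    if (ok) break
  }
  m <- nb_train(pos, neg, alpha = 0)
  X <- data.frame(apply(rbind(pos, neg), 2, factor, levels = c(0, 1)))
  y <- factor(rep(c("pos", "neg"), c(30, 40)), levels = c("neg", "pos"))
  fit <- e1071::naiveBayes(X, y, laplace = 0)
  for (rep in 1:20) {
    x <- rand_bin(1, d)[1, ]
    nd <- data.frame(lapply(x, factor, levels = c(0, 1)))
    names(nd) <- names(X)
    ref <- predict(fit, nd, type = "raw")[1, "pos"]
    expect_equal(nb_posterior(m, x), unname(ref), tolerance = 1e-9)
  }
})

test_that("candidate classification partitions the pool", {
  corp <- small_corpus()
  st <- snippet_store(corp$snippets_path)
  seeds <- load_dictionary(corp$seeds_path, "en")
  pats <- select_top_patterns(
    mine_patterns(st, seeds, "MEDICATION", "en"), 30)
  pos_terms <- seeds$entries$MEDICATION
  neg_terms <- corp$vocab$distractors$surface[1:25]
  fz <- function(tm) featurize(tm, fetch_snippets(st, tm), pats, "en")
  m <- nb_train(t(vapply(pos_terms, fz, integer(nrow(pats)))),
                t(vapply(neg_terms, fz, integer(nrow(pats)))))
  pool_terms <- c(corp$vocab$terms$surface[
    corp$vocab$terms$category == "MEDICATION"][1:20],
    corp$vocab$distractors$surface[30:40])
  pool <- aggregate_candidates(list(mk_list(pool_terms)), "MEDICATION")
  res <- classify_candidates(pool, st, pats, m, 0.5, "en")
  expect_setequal(c(res$accepted, res$rejected), names(pool$terms))
  expect_length(intersect(res$accepted, res$rejected), 0L)
  # an informative model rejects snippetless candidates
  rare <- corp$vocab$terms$surface[corp$vocab$terms$is_rare &
    corp$vocab$terms$category == "MEDICATION"][1]
  rare_pool <- aggregate_candidates(list(mk_list(rep(rare, 2))),
                                    "MEDICATION")
  res2 <- classify_candidates(rare_pool, st, pats, m, 0.5, "en")
  expect_identical(res2$accepted, character(0))
})

test_that("pattern TSV and model JSON round-trip exactly", {
  df <- data.frame(tokens = c("side effects", "说 明"),
                   side = c("follows", "precedes"), N_p = c(5L, 2L),
                   N_o = c(1L, 0L), score = c(3.25, 1.5),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_patterns(df, f)
  expect_identical(read_patterns(f), df)
  m <- nb_train(rand_bin(5, 3), rand_bin(4, 3))
  g <- withr::local_tempfile(fileext = ".json")
  nb_save(m, g)
  m2 <- nb_load(g)
  expect_equal(unname(m$cond_pos), m2$cond_pos, tolerance = 1e-15)
  expect_equal(m$prior_pos, m2$prior_pos, tolerance = 1e-15)
})
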