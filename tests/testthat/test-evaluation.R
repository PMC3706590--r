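toy_ref <- function() {
  reference_corpus(data.frame(
    surface = c("chronic obstructive pulmonary disease", "copd",
                "aspirin"),
    category = "PROBLEM",
    object_id = c("O1", "O1", "O2"),
    head = c("disease", "copd", "aspirin"),
    stringsAsFactors = FALSE), "en")
}

test_that("toy fixture reproduces hand-counted recalls", {
  # dictionary holds the full form (not the abbreviation) and an
  # unrelated surface whose head matches nothing in the reference
  dict <- c("chronic obstructive pulmonary disease", "ibuprofen",
            "renal failure")
  ref <- toy_ref()
  rs <- surface_recall(dict, ref)
  expect_identical(rs$TP, 1L)
  expect_equal(rs$R_S, 1 / 3, tolerance = 1e-15)
  ro <- object_recall(dict, ref)
  expect_identical(ro$TP, 1L)
  expect_equal(ro$R_O, 1 / 2, tolerance = 1e-15)
  hx <- function(term) default_head_extractor(
    term, "en", modifier_lexicon = c("chronic", "obstructive",
                                     "pulmonary", "renal"),
    head_lexicon = c("disease", "failure"))
  rh <- head_recall(dict, ref, hx)
  # reference heads: disease (matched by dict full form), copd (no),
  # aspirin (no) -> 1/3
  expect_identical(rh$TP, 1L)
  expect_equal(rh$R_H, 1 / 3, tolerance = 1e-15)
})

test_that("head matching credits shared heads across different surfaces", {
  ref <- reference_corpus(data.frame(
    surface = "brain lesion", category = "PROBLEM", object_id = "O1",
    head = "lesion", stringsAsFactors = FALSE), "en")
  hx <- function(term) default_head_extractor(
    term, "en", modifier_lexicon = c("brain", "spinal"),
    head_lexicon = "lesion")
  rh <- head_recall(c("spinal lesion"), ref, hx)
  expect_identical(rh$R_H, 1)
  expect_identical(head_recall("unrelated", ref, hx)$R_H, 0)
})

test_that("object recall quotients surface matches onto synonym classes", {
  set.seed(15)
  for (rep in 1:25) {
    n <- sample(5:15, 1)
    surf <- paste0("t", 1:n)
    obj <- paste0("O", sample(ceiling(n / 2), n, TRUE))
    ref <- reference_corpus(data.frame(
      surface = surf, category = "TEST", object_id = obj,
      head = surf, stringsAsFactors = FALSE), "en")
    dict <- sample(surf, sample(1:n, 1))
    ro <- object_recall(dict, ref)
    # covered objects are exactly the classes of surface-matched terms
    expect_identical(ro$TP, length(unique(obj[surf %in% dict])))
    # with singleton classes the two recalls coincide
    ref1 <- reference_corpus(data.frame(
      surface = surf, category = "TEST", object_id = paste0("S", 1:n),
      head = surf, stringsAsFactors = FALSE), "en")
    expect_equal(object_recall(dict, ref1)$R_O,
                 surface_recall(dict, ref1)$R_S, tolerance = 1e-15)
  }
})

test_that("precision and err are census-exact M/N estimators", {
  truth <- c("a", "b", "c")
  suppressMessages({
    p <- precision_estimate(c("a", "b", "c", "x"), truth, n_sample = 100)
  })
  expect_equal(p$P, 3 / 4)
  expect_identical(p$N, 4L)
  p2 <- precision_estimate(letters[1:10], function(x) rep(TRUE, length(x)),
                           n_sample = 5, rng_seed = 2)
  expect_identical(p2$P, 1)
  # sampled estimate is deterministic under the seed
  big <- paste0("w", 1:500)
  pa <- precision_estimate(big, big[1:250], n_sample = 100, rng_seed = 7)
  pb <- precision_estimate(big, big[1:250], n_sample = 100, rng_seed = 7)
  expect_identical(pa$sample, pb$sample)
  suppressMessages({
    e <- err_estimate(c("a", "x", "y", "z"), truth, n_sample = 10)
  })
  expect_equal(e$Err, 1 / 4)
  expect_error(precision_estimate(character(0), truth), "empty")
})

test_that("F measures are harmonic means with the zero convention", {
  expect_identical(f_measure(1, 1), 1)
  expect_identical(f_measure(0.5, 0.5), 0.5)
  expect_identical(f_measure(0, 0), 0)
  expect_equal(f_measure(0.9, 0.3), 2 * 0.9 * 0.3 / 1.2, tolerance = 1e-15)
})

test_that("head extractor recovers generated heads and falls back sanely", {
  expect_identical(
    default_head_extractor("慢性阻塞性肺炎", "zh",
                           modifier_lexicon = c("慢性", "阻塞性"),
                           head_lexicon = "肺炎"),
    "肺炎")
  expect_identical(default_head_extractor("lesion", "en",
                                          head_lexicon = "lesion"),
                   "lesion")
  expect_identical(default_head_extractor("odd thing", "en"), "odd thing")
  # generative oracle: compounds built from the synthetic lexicons
  corp <- small_corpus()
  t <- corp$vocab$terms
  hx <- function(term) default_head_extractor(
    term, "en", corp$vocab$modifier_lexicon, corp$vocab$head_lexicon)
  idx <- sample(nrow(t), 30)
  expect_identical(vapply(t$surface[idx], hx, character(1),
                          USE.NAMES = FALSE), t$head[idx])
})

test_that("reports audit internally: F from stored P and R to 1e-12", {
  ref <- toy_ref()
  dict <- c("chronic obstructive pulmonary disease", "aspirin")
  suppressMessages({
    rep_ <- evaluation_report(dict, ref,
                              truth_oracle = ref$surface,
                              removed = c("junk1", "junk2", "copd"),
                              head_extractor = function(x) x,
                              n_sample = 10)
  })
  expect_equal(rep_$F_S, f_measure(rep_$P, rep_$R_S), tolerance = 1e-12)
  expect_equal(rep_$F_O, f_measure(rep_$P, rep_$R_O), tolerance = 1e-12)
  expect_equal(rep_$F_H, f_measure(rep_$P, rep_$R_H), tolerance = 1e-12)
  expect_equal(rep_$P, rep_$P_counts[["M"]] / rep_$P_counts[["N"]],
               tolerance = 1e-15)
  expect_equal(rep_$R_S,
               rep_$R_S_counts[["TP"]] / rep_$R_S_counts[["N"]],
               tolerance = 1e-15)
  expect_equal(rep_$Err,
               rep_$Err_counts[["M"]] / rep_$Err_counts[["N"]],
               tolerance = 1e-15)
})
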