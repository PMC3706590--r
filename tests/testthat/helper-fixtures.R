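# Shared fixture builders. Everything is generated in code at test time;
# corpora are cached per-session under tempdir() so several test files
# can reuse them without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

#' Generate (once per session) and return a synthetic corpus.
cached_corpus <- function(key, cfg) {
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("termharvest-", key))
    .fixture_cache[[key]] <- gen_corpus(cfg, dir)
  }
  .fixture_cache[[key]]
}

# Reduced-scale corpus for module-level pipeline tests.
small_corpus <- function() {
  cached_corpus("small", corpus_config(
    n_true_terms = 60L, n_seed_terms = 25L, n_pages = 12L,
    items_per_list = 120L, rng_seed = 42L))
}

# The default study conditions (used by the end-to-end checks).
default_corpus <- function() {
  cached_corpus("default", corpus_config(rng_seed = 42L))
}

cached_run <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

# Quick candidate-list builder.
mk_list <- function(items, list_id = "p1-L001", page_id = "p1",
                    path = "html.empty/body.empty/div.x", language = "en",
                    hits = character(0)) {
  l <- structure(list(list_id = list_id, page_id = page_id, path = path,
                      items = items, hits = hits, H_L = length(hits),
                      N_L = length(items),
                      mean_len = mean(term_length(items, language)),
                      language = language), class = "candidate_list")
  l
}

# Random small DOM generator with known expected grouping. Returns the
# HTML string and a data.frame (path, item) of expected text nodes.
rand_dom <- function(max_children = 4L, max_depth = 3L) {
  # tags restricted to ones whose nesting libxml2 never restructures;
  # adjacent text leaves are avoided (the parser would merge them)
  tags <- c("div", "span", "em", "b", "i")
  classes <- c(NA, NA, "a", "b", "a b", "c")
  words <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta")
  paths <- character(0)
  items <- character(0)
  build <- function(depth, path) {
    n <- sample(0:max_children, 1)
    out <- character(0)
    last_was_text <- FALSE
    for (i in seq_len(n)) {
      want_text <- depth >= max_depth || stats::runif(1) < 0.45
      if (want_text && last_was_text) next
      if (want_text) {
        last_was_text <- TRUE
        w <- paste(sample(words, sample(1:2, 1)), collapse = " ")
        paths <<- c(paths, path)
        items <<- c(items, w)
        out <- c(out, w)
      } else {
        last_was_text <- FALSE
        tag <- sample(tags, 1)
        cls <- sample(classes, 1)
        seg <- if (is.na(cls)) paste0(tag, ".empty") else {
          paste0(tag, ".", paste(sort(strsplit(cls, " ")[[1]]),
                                 collapse = "+"))
        }
        attr_s <- if (is.na(cls)) "" else sprintf(' class="%s"', cls)
        inner <- build(depth + 1L, paste0(path, "/", seg))
        out <- c(out, sprintf("<%s%s>%s</%s>", tag, attr_s,
                              paste(inner, collapse = ""), tag))
      }
    }
    out
  }
  body <- build(1L, "html.empty/body.empty")
  list(html = paste0("<html><body>", paste(body, collapse = ""),
                     "</body></html>"),
       expected = data.frame(path = paths, item = items,
                             stringsAsFactors = FALSE))
}

# Toy snippet data.frame.
mk_snips <- function(contexts) {
  data.frame(term = rep("x", length(contexts)),
             rank = seq_along(contexts),
             title = character(length(contexts)),
             url = character(length(contexts)),
             context = as.character(contexts), stringsAsFactors = FALSE)
}

# Random 0/1 matrix.
rand_bin <- function(n, d, p = 0.5) {
  matrix(as.integer(stats::runif(n * d) < p), nrow = n)
}
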