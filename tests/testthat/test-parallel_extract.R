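test_that("text nodes group by tag-class path into candidate lists", {
  html <- paste0(
    "<html><body><ul>",
    paste0('<li class="name">Drug ', 1:5, "</li>",
           '<li class="price">price ', 1:5, "</li>", collapse = ""),
    "</ul></body></html>")
  lists <- extract_candidate_lists(html, "p1", "en")
  expect_length(lists, 2L)
  expect_setequal(vapply(lists, function(l) l$N_L, integer(1)), c(5L, 5L))
  expect_true(any(grepl("li.name", vapply(lists, `[[`, character(1),
                                          "path"), fixed = TRUE)))

  # every node on a distinct path -> no group reaches size 2
  html2 <- "<html><body><div><p>a</p></div><span>b</span></body></html>"
  expect_length(extract_candidate_lists(html2, "p2", "en"), 0L)
})

test_that("multi-valued classes canonicalize and script/style are excluded", {
  html <- paste0('<html><body>',
                 '<div class="b a">x1</div><div class="a  b">x2</div>',
                 "<script>var a = 1;</script><style>.a{}</style>",
                 "</body></html>")
  lists <- extract_candidate_lists(html, "p1", "en")
  expect_length(lists, 1L)
  expect_match(lists[[1]]$path, "div\\.a\\+b$")
  expect_setequal(lists[[1]]$items, c("x1", "x2"))
})

test_that("grouping matches a generative oracle on random small DOMs", {
  set.seed(101)
  for (rep in 1:60) {
    dom <- rand_dom()
    if (!nrow(dom$expected)) next
    got <- extract_candidate_lists(dom$html, "p", "en", min_items = 1L)
    exp_groups <- split(tolower(dom$expected$item), dom$expected$path)
    got_groups <- lapply(got, `[[`, "items")
    names(got_groups) <- vapply(got, `[[`, character(1), "path")
    expect_identical(length(got_groups), length(exp_groups))
    for (p in names(exp_groups)) {
      expect_identical(sort(got_groups[[p]]), sort(exp_groups[[p]]))
    }
    # partition property: group sizes sum to number of text nodes
    expect_identical(sum(lengths(got_groups)), nrow(dom$expected))
  }
})

test_that("tag soup never raises and unparseable input warns", {
  soup <- "<html><body><div><p>a<p>b<div>c</body>"
  expect_silent(extract_candidate_lists(soup, "p1", "en"))
  expect_warning(extract_candidate_lists(character(0), "p2", "en"),
                 "unparseable")
})

test_that("list selection keeps strictly more than k seed hits", {
  seeds <- paste0("s", 1:20)
  l11 <- mk_list(c(paste0("s", 1:11), "x"))
  l10 <- mk_list(c(paste0("s", 1:10), "x"), list_id = "p1-L002")
  kept <- select_lists(list(l11, l10), seeds, k = 10)
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$list_id, "p1-L001")
  expect_identical(kept[[1]]$H_L, 11L)
  expect_length(select_lists(list(l11), character(0), k = 0), 0L)

  # randomized instances against a brute-force set-intersection oracle
  set.seed(21)
  for (rep in 1:50) {
    items <- sample(paste0("w", 1:30), sample(5:25, 1), replace = TRUE)
    sds <- sample(paste0("w", 1:30), 10)
    k <- sample(0:5, 1)
    got <- select_lists(list(mk_list(items)), sds, k)
    brute <- length(unique(items)[unique(items) %in% sds])
    expect_identical(length(got) == 1L, brute > k)
    if (length(got)) expect_identical(got[[1]]$H_L, brute)
  }
})

test_that("cleanup removes long or punctuated items and is idempotent", {
  l <- mk_list(c("aspirin", "aspirin, 100 mg daily dose taken orally"),
               hits = "aspirin")
  c1 <- clean_list(l, "en", max_len = 6, punct_set = default_punct_set())
  expect_identical(c1$items, "aspirin")
  expect_identical(c1$N_L, 1L)
  expect_identical(c1$H_L, 1L)
  clean <- mk_list(c("chest pain", "x-ray"))
  expect_identical(clean_list(clean, "en")$items, clean$items)
  c2 <- clean_list(c1, "en", max_len = 6, punct_set = default_punct_set())
  expect_identical(c2$items, c1$items)

  # per-item brute-force oracle on random item sets
  set.seed(5)
  punct <- default_punct_set()
  for (rep in 1:50) {
    items <- replicate(10, paste(
      sample(c("ab", "cd,", "efg", "h.i", "jk"),
             sample(1:9, 1), replace = TRUE), collapse = " "))
    items <- normalize_term(items, "en")
    got <- clean_list(mk_list(items), "en", max_len = 4,
                      punct_set = punct)$items
    keep <- vapply(items, function(it) {
      term_length(it, "en") <= 4 &&
        !any(strsplit(it, "")[[1]] %in% punct)
    }, logical(1))
    expect_identical(got, unname(items[keep]))
  }
})

test_that("aggregation keys by surface with exact provenance", {
  l1 <- mk_list(c("a", "b", "c", "d"), list_id = "p1-L1", page_id = "p1")
  l2 <- mk_list(c("c", "e", "f", "g", "h"), list_id = "p2-L1",
                page_id = "p2")
  pool <- aggregate_candidates(list(l1, l2), "PROBLEM")
  expect_length(pool$terms, 8L)
  expect_identical(pool$terms[["c"]]$sources,
                   list(c("p1", "p1-L1"), c("p2", "p2-L1")))

  # inverted-index oracle on random lists
  set.seed(33)
  for (rep in 1:40) {
    lists <- lapply(1:4, function(i) {
      mk_list(sample(letters[1:10], sample(2:8, 1), replace = TRUE),
              list_id = paste0("L", i), page_id = paste0("p", i))
    })
    pool <- aggregate_candidates(lists, "TEST")
    brute <- list()
    for (l in lists) {
      for (s in unique(l$items)) {
        brute[[s]] <- union(brute[[s]], paste(l$page_id, l$list_id))
      }
    }
    expect_identical(sort(names(pool$terms)), sort(names(brute)))
    for (s in names(brute)) {
      expect_setequal(vapply(pool$terms[[s]]$sources, paste,
                             character(1), collapse = " "), brute[[s]])
    }
  }
})
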