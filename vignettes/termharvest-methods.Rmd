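---
title: "Building medical term dictionaries from parallel web structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building medical term dictionaries from parallel web structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical text processing needs large dictionaries of the terms that
actually occur in medical records — medical problems, medications, and
medical tests — and curated resources cover only the formal subset of
them. `termharvest` expands a small, high-precision seed dictionary into
a large collection by exploiting *parallel structures* on the web:
tables, lists, navigation bars, and index pages that enumerate entities
of one type. The package implements the complete pipeline for both
Chinese-like (character-based) and English-like (word-based) settings,
with dedicated evaluation metrics and a seeded synthetic corpus so every
stage runs and is testable offline.

## The pipeline

1. **Query generation.** Two-seed queries (`generate_query_pairs()`):
   pages matching two terms of one category very likely enumerate that
   category. Offline, a `page_store()` stands in for the search engine.
2. **Parallel-structure mining.** `extract_candidate_lists()` groups the
   text nodes of a page by *tag-class path* — the root-to-node sequence
   of (tag, class) pairs, class `"empty"` where absent. Equal paths mean
   analogous positions and typography; each group of two or more nodes
   becomes a candidate list.
3. **List selection and cleanup.** `select_lists()` keeps lists whose
   hit count `H_L` (distinct seed terms among the items) is strictly
   greater than `k = 10`; `clean_list()` drops items that are too long
   (over `3 * l_p`) or contain punctuation.
4. **Aggregation.** `aggregate_candidates()` pools items with exact
   `(page, list)` provenance, which later scoring consumes.
5. **Noise filtering.** Two systems share steps 1–4:
   - the **baseline** system classifies every candidate by snippet
     context alone;
   - the **combined** system first admits whole high-quality lists,
     scores the remaining candidates by form, deletes the worst outright,
     and sends only the rest to snippet analysis.
6. **Re-seeding.** Accepted terms are merged into the dictionary and act
   as seeds in the next iteration (default `max_iterations = 2`).

## The scoring components

**Contextual pattern score.** A pattern is an n-gram (n < 6) immediately
following the query term at the very beginning of a snippet context, or
immediately preceding it at the very end; occurrences elsewhere are
ignored so no term-boundary detection is needed. With `N_p` in-class
occurrences, `O` other-class seeds, and `N_o` other-class seeds showing
the pattern, the effectiveness score is

    score(P) = N_p * log((O + 1) / (N_o + 1)),

a TF/IDF-like trade-off: zero without in-class evidence, zero when the
pattern is ubiquitous in the other classes. The 50 top patterns per
category become binary features of a Bernoulli naive Bayes classifier
(priors = class proportions, conditionals Laplace-smoothed as
`(count + alpha) / (n_class + 2 alpha)`), trained with seeds as
positives and items sampled from zero-hit lists as negatives.

**Length fitness.** `f(l) = 1` for `l <= l_p`, else
`exp(-c (l - l_p))`, with proper length `l_p` = 2 English words / 5
Chinese characters. The defining condition for `c` is the calibration
`f(2 l_p) = f_floor` (default 0.1), i.e. `c = -log(f_floor) / l_p`;
`f_floor` is exposed in the configuration.

**List quality.** `S_q(L) = (H_L / log2(2 + N_L)) * f(mean_len)`: linear
in the hit count but only logarithmic in the list size, because hits
matter more than length. The combined system ranks lists by `S_q`, takes
the top 200, and admits *wholesale* every item of those with more than
100 entities — the step that recovers terms too rare for snippet
analysis to see.

**Entity score.** For a candidate on `M` lists,

    S(E) = f(l_E) * g(C_E) * A(C_E) * sum_i S_q(L_i),

where `g` is a hard part-of-speech gate (0 iff the candidate contains a
pronoun PRP, particle RP, or question word WP/WRB) and `A` is the
posterior of an affix naive Bayes over the 20 most frequent
prefixes/suffixes of the category's seeds (1–5 English letters, 1–3
Chinese characters). Candidates below the deletion threshold are
discarded without snippet processing; the remainder is deferred to the
snippet classifier.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | list selection: seed hits must exceed this |
| `l_p` | 2 en words / 5 zh chars | proper term length |
| `f_floor` | 0.1 | fitness at twice the proper length |
| `max_len` | `3 * l_p` | cleanup length cap |
| `m_patterns` | 50 | context-pattern features per category |
| `m_affixes` | 20 | affix features per category |
| `top_lists` | 200 | lists ranked for wholesale acceptance |
| `min_list_entities` | 100 | wholesale floor (strictly greater) |
| `accept_top_entities` | 0 | outright score-rank acceptances |
| `delete_below` | 25th percentile of `S(E)` | pre-snippet deletion |
| `nb_threshold` | 0.5 | snippet-classifier acceptance posterior |
| `max_iterations` | 2 | re-seeding rounds |

The deletion threshold and the score-rank acceptance count are design
choices: the originating description leaves both unnamed, so the package
defaults to relying on wholesale lists (`accept_top_entities = 0`) and a
data-driven percentile cut, both recorded per run.

## What the synthetic corpus emulates — and what it does not

`gen_corpus()` builds, under one master seed, a miniature web whose
statistical structure matches what each stage assumes: true terms are
modifier+head compositions carrying category-typical affixes ("-scopy"
tests, "-itis" problems) with probability `affix_prob`; each page holds
a term column (seeds and unseen true terms) plus sibling dosage/code
columns under distinct tag-class paths; snippets emit category boundary
patterns with probability 0.9 for true terms and 0.05 (random category)
for distractors; a rare stratum (20% of non-seed terms) appears on lists
but has no snippets, reproducing the regime where snippet analysis alone
must fail; surface variants share reference objects; encyclopedia
entries carry tags, related links, and page-rule keywords.

`distractor_rate` is the per-slot probability that a term-column slot
holds a distractor, so a zero rate yields pure term columns; the sibling
distractor columns are always present, mimicking the
name/approval-number/dosage page layout. The default conditions are 3
categories × 200 true terms (80 seeds), 50 pages with 200-item term
columns, and distractor rate 0.5.

The generator does **not** mimic real web boilerplate (ads, navigation
chrome), search-engine ranking noise, encoding errors, or genuinely
ambiguous term boundaries. Passing end-to-end tests therefore
demonstrates that the machinery implements the method correctly under
its stated assumptions, not that the same precision/recall would be
obtained on the live web.

## Numerical and design choices

- **English is matched case-insensitively** on NFC-normalized,
  whitespace-collapsed surfaces; Chinese verbatim. Both sides of every
  seed/item comparison are normalized.
- **Multi-valued class attributes** canonicalize to the sorted token set
  joined by `+`; a text node is a maximal text run directly under one
  element, never concatenated across children.
- **`H_L` counts distinct matched items**, not occurrences.
- **Ties** are broken deterministically everywhere: pattern selection by
  (score, `N_p`, tokens), list ranking by (`S_q`, `H_L`, list id), gate
  acceptance by (`S_E`, term). Outputs are invariant to input order.
- **Classifiers are trained once per category on the initial seeds** and
  reused across iterations; retraining on self-expanded seeds would feed
  accepted noise back into the models.
- **Degenerate inputs**: unparseable HTML yields an empty result with a
  warning; a term with no snippets is scored on the all-zero vector (for
  an informative model this is negative evidence); an empty dictionary
  file loads as an empty dictionary with a warning; posteriors are
  computed in log space.
- **POS tagging is a contract**: any `function(tokens) -> tags` over a
  tagset containing NN/PRP/RP/WP/WRB plugs in; the package ships a
  deterministic lexicon-based toy tagger for reproducible tests.
- The affix example "-copy" shows that affixes of *every* length up to
  the cap are generated (lengths 1–5 en / 1–3 zh), not only the maximal
  one.

## Evaluation metrics

Surface recall `R_S` is exact-match recall; object recall `R_O` is the
fraction of reference synonym classes with at least one surface in the
dictionary; head recall `R_H` matches head nouns (term minus modifiers
under an is-a relation), crediting productive formations like "body
part + problem". Precision `P` and the false-discard rate `Err` are
`M/N` estimators over seeded random samples, reviewed here by a truth
oracle (label files) instead of human judges; `N` is a parameter. Note
that `R_O >= R_S` is *not* a theorem — collapsing surfaces into objects
shrinks numerator and denominator differently — although it typically
holds in practice; the package checks the exact quotient property
instead.

## Problem sizes used by the shipped checks

Module tests run on corpora of 60 true terms × 12 pages; the end-to-end
checks use the default conditions above (600 true terms, 50 pages,
~11,000 planted items) and complete in well under a minute per run. The
randomized oracle-equivalence suites use 200 instances per operation at
up to 50 DOM nodes and 6 classifier features.

## Known limitations

- Live crawling, snippet retrieval, and machine translation are out of
  scope by design; the store contracts replace them.
- The toy POS tagger covers only the closed classes the gate needs;
  production use should plug in a real tagger.
- Patterns and classifiers are monolingual per run; bilingual models are
  not supported.
- Wholesale list acceptance deliberately trusts high-`S_q` lists without
  per-item filtering, so list-level contamination that survives cleanup
  passes through — the price of recovering rare terms.
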