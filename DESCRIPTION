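Package: termharvest
Title: Building Large Medical Term Dictionaries from Parallel Web Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for expanding a small seed dictionary of medical terms
    (Problems, Medications, Tests) into a large term collection by mining
    parallel structures (tables, lists, index pages) from crawled HTML.
    Text nodes sharing a tag-class DOM path are grouped into candidate
    lists, lists holding many known seed terms are selected and cleaned,
    and three noise filters are combined to keep valid terms: a
    snippet-context naive Bayes classifier built from mined contextual
    n-gram patterns, a list-quality score that admits whole high-quality
    lists, and a form-based entity score combining length fitness, a
    part-of-speech gate, and an affix classifier. Includes iterative
    re-seeding, dedicated evaluation metrics (surface, object, and head
    recall plus a false-discard error rate), and a fully seeded synthetic
    corpus generator so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils,
    xml2
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
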