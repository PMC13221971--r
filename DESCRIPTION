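Package: mednorm
Title: Normalization of Free-Text Medication Strings to Ingredient-Level Drug Concepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps messy free-text medication strings (brand names, abbreviations,
    misspellings, truncations, dose suffixes, multi-ingredient products) to
    ingredient-level generic drug concepts (IN/MIN) in a local RxNorm-like
    knowledge base. Candidate generation combines deterministic token-set
    Jaccard matching against a synonym index with a pluggable parser backend
    that emits generic ingredient names; the two candidate sets are fused by a
    three-tier hierarchical reconciliation (perfect, normalized-perfect, and
    greedy subset match) with rule-based confidence labels. Finalized concepts
    are annotated with ATC codes under ingredient-identity validation, and
    mappings are scored against gold standards with micro-averaged
    precision/recall/F1 at both the concept and the ingredient level. Includes
    a seeded generator of synthetic knowledge bases and corrupted-string
    benchmarks for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
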