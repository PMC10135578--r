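Package: ecmdiseasome
Title: Gene-Disease Network Analysis of the Human Matrisome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating the matrisome diseasome:
    readers for matrisome gene catalogs, clinical variant tables, PheWAS
    catalog extracts, gene-disease association sets, drug-gene links,
    rare-disease records and protein-protein interaction pair lists;
    annotation of any gene-bearing table against a matrisome catalog;
    parsing of protein-level variant notation into amino-acid substitution
    matrices with collagen Gly-X-Y periodicity checks; substring-based
    disease categorization into connective-tissue, common and age-related
    groups; bipartite gene-disease network construction with degree
    summaries and shared-disease clustering; drug-repurposing candidate
    joins; and a seeded synthetic-data generator that plants machine-readable
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
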