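Package: coocnet
Title: Ingredient Co-Occurrence Networks from Product Notification Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ingredient co-occurrence networks from tab-delimited
    product-ingredient tables of the kind exported from regulatory
    notification systems such as the European Common Entry Gate (EU-CEG).
    Provides ingredient-name curation and synonym merging, prevalence
    filtering, all-pairs 2x2 contingency screening with sample and
    conditional maximum-likelihood odds ratios, a compound significance
    rule (minimum co-occurrence count and minimum odds ratio), a
    column-permutation null for false-positive calibration, network
    construction and summary statistics, MCODE dense-cluster detection,
    cross-product-type overlap reports, and a synthetic-data generator
    with planted flavor-category structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
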