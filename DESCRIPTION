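Package: herbnet
Title: Network Pharmacology Screening and Platelet Dose-Response Analysis
    for Multi-Herb Prescriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style toolkit for network-pharmacology inference on
    multi-herb prescriptions: QED drug-likeness and Veber oral-bioavailability
    screening of phytochemicals, intersection of predicted compound targets
    with disease gene lists, protein-protein interaction topology (degree,
    betweenness, closeness) with threshold-based key-target selection,
    hypergeometric pathway over-representation with Benjamini-Hochberg
    control, integrated herb-compound-target-pathway network ranking,
    monoisotopic adduct m/z identification arithmetic, and four-parameter
    logistic IC50 fitting of platelet-aggregation dose-response data.
    Includes a seeded synthetic-study generator with planted ground truth so
    the whole pipeline can be exercised and validated without any database
    access.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
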