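Package: oromicro
Title: Oral Tumor Microbiome Analysis with Paired Differential Genus Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-specimen oral-cancer microbiome
    studies. Implements an alignment-based paired differential-genus caller
    for matched specimens from the same patients (predominant-genus
    filtering, pseudocount-protected fold changes, majority two-fold calls),
    Shannon alpha diversity with rank-based group tests, Bray-Curtis beta
    diversity with principal coordinate analysis and a permutation PERMANOVA,
    a within- versus between-patient clustering test, composition summaries,
    a clinicopathology association screen reproducing chi-square contingency
    analysis of a 218-patient cohort, and a logistic-normal-multinomial
    simulator for paired microbiome studies and clinical cohorts with known
    planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
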