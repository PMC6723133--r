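Package: lohscreen
Title: Statistical Pipeline for Yeast Loss-of-Heterozygosity Deletion Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for genome-wide heterozygous-deletion screens for
    loss of heterozygosity (LOH) in Saccharomyces cerevisiae: ordinal scoring of
    mating-plate colony counts and top-hit calling, sectoring-assay threshold
    derivation and positive calls, hypergeometric overlap statistics between
    screens (expected overlap, representation factor, directional tail
    probability), Fisher/Benjamini-Hochberg gene-ontology term enrichment with
    slim-term rollup, positional gene enrichment scans for hit-dense
    chromosomal intervals, and Luria-Delbruck fluctuation analysis
    (Ma-Sandri-Sarkar likelihood, profile-likelihood confidence intervals, LOH
    rates and fold changes). A synthetic-data generator reproduces the
    statistical structure of every input so the whole pipeline is testable
    without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
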