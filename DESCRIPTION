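Package: neffbiome
Title: Nitrogen-Efficiency Phenotyping and Gut Microbiome Association
    Analysis for Dairy Cows
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to phenotype lactating dairy cows for nitrogen
    efficiency (milk N as a percentage of N intake) from a nitrogen
    balance built on marker-based digestibility and creatinine-estimated
    urine volume, and to relate the phenotype to rumen and fecal 16S rRNA
    bacterial communities. Includes rarefaction, alpha diversity
    (observed features, Shannon, Pielou, Good's coverage), weighted
    UniFrac with principal coordinate analysis and PERMANOVA, LEfSe-style
    differential abundance detection, correlation analysis with
    Benjamini-Hochberg false discovery rate control, and a seeded
    synthetic-data generator that emulates the statistical structure of
    such a study for testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phyloseq,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
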