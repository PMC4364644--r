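Package: methduet
Title: Dual-Model Differential Methylation Discovery for Infinium Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for epigenome-wide differential
    methylation discovery on Infinium-style beta-value matrices: detection
    p-value and probe-flag quality control, beta to M-value transformation,
    quantile normalization, CpG-island collapsing into interrogated
    locations, covariate-adjusted robust linear models with empirical-Bayes
    moderated t-statistics for two contrasts (weight category and SNP
    genotype dose), Benjamini-Hochberg adjustment, and candidate-gene
    nomination by intersecting the two models' top-ranked locations. A
    synthetic-cohort simulator with configurable spiked effects makes every
    stage testable without external data.
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
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
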