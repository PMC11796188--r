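Package: mediomics
Title: High-Dimensional Mediation Analysis for Omics Studies of Breast Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how circulating metabolites and lipid species
    mediate the association between early-life body mass index and volumetric
    mammographic breast density in premenopausal cohorts. Provides a synthetic
    cohort generator built on the structural equations of high-dimensional
    mediation, omics preprocessing (missingness filtering, k-nearest-neighbour
    imputation, empirical-Bayes batch adjustment, log10 transformation with
    unit-SD scaling, chained-equation covariate imputation), per-feature
    covariate-adjusted association scans with false-discovery-rate control, and
    a from-scratch high-dimensional mediation engine combining sure
    independence screening, minimax-concave-penalty selection, joint
    significance testing and proportion-of-total-effect estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
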