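Package: sparsemet
Title: Genetic Analysis of Sparse Multi-Environment Trial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for quantitative-genetic analysis of sparse,
    unbalanced multi-environment trial (MET) networks such as long-running
    cooperative crop nurseries. Harmonizes heterogeneous trait scales and
    removes outlier location-by-year cells; estimates kinship-conditioned
    best linear unbiased predictions (BLUPs) and narrow-sense heritability
    by restricted maximum likelihood with location and location-by-year
    fixed effects; runs mixed-linear-model genome-wide association scans
    with BIC-based principal-component selection and Benjamini-Hochberg
    false-discovery-rate control; applies empirical-Bayes multivariate
    shrinkage across phenotypes (covariance-mixture prior, local false-sign
    rates, Bayes factors, pairwise effect sharing); and compares association
    catalogs across studies by distance-based overlap clustering. Includes a
    synthetic-data generator emulating the statistical structure of a sparse
    inbred diversity panel so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
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
    vcfR,
    yaml
Suggests:
    knitr,
    mvtnorm,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
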