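Package: variophen
Title: Variogram-Based Texture Phenotyping of Lung CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lung parenchymal texture on masked chest CT through
    within-slice empirical variograms and weighted-least-squares fits of
    exponential and Matern variogram models, then phenotypes subjects by
    sparse diagonal Gaussian mixture clustering with per-feature relevance
    selection (BIC or MICL). Includes slice trimming and decile slice
    selection, ComBat-style empirical-Bayes scanner harmonization that
    preserves clinical covariates, feature-robustness metrics (ICC(3,1),
    Spearman), cluster association statistics (bias-corrected Cramer's V,
    simulated Fisher tests), and outcome models (linear regression with
    likelihood-ratio tests, Firth penalized logistic regression with
    penalized likelihood-ratio tests). A synthetic-cohort generator draws
    Gaussian random fields with known Matern covariance, planted phenotype
    clusters, scanner batch effects, and linked lung-function and
    visual-score outcomes, so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    mclust,
    RNifti
Config/testthat/edition: 3
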