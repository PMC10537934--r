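Package: echodens
Title: Predicting Percent Mammographic Density from B-Mode Ultrasound Texture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for estimating percent mammographic
    density (PMD) from gray-level histogram features of B-mode breast
    ultrasound images. Provides a synthetic-cohort generator with known
    ground truth (latent density, two-reader PMD outcome, speckled
    two-tissue echotexture with skin and muscle bands), region-of-interest
    extraction via the largest axis-aligned rectangle in a binary mask,
    pooled 256-level gray histograms reduced to sixteen equal gray-level
    bins (the darkest bin omitted as redundant), a suite of eight
    regression models from the intercept-only null model to a random
    forest, and a repeated three-fold cross-validation harness reporting
    apparent and cross-validated mean squared error and R-squared,
    per-bin Spearman correlations, and a train/validation hold-out
    illustration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    png,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
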