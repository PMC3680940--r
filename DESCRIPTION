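Package: mammodensity
Title: Automated Mammographic Density Measurement from Digitized Mammograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fully automated pipeline for measuring mammographic density
    on digitized film mammograms. Extracts the breast region by grayscale
    morphology and minimum-error thresholding, computes a fixed-layout
    feature vector under a suite of fifteen global histogram thresholding
    algorithms with watershed particle analysis, reduces features by
    principal components, trains a lasso model that mimics a reference
    percent-density read, builds penalized-logistic risk scores carrying
    information beyond percent density, and evaluates agreement and
    discrimination (Pearson/Fisher, Bland-Altman, odds-ratio profiles,
    ROC/DeLong, deviance/likelihood-ratio tables). Includes a seeded
    phantom-image generator so every stage is testable with known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
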