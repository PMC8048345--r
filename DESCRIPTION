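Package: trajsurv
Title: Sparse Cox Gene Selection and Alignment-Kernel Clustering of
    Longitudinal Expression Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Couples penalized survival modelling with multivariate
    time-series clustering for longitudinal transcriptomics cohorts whose
    outcome is a time-to-event (for example, hospital length of stay).
    Provides elastic-net Cox regression fitted by cyclical coordinate
    descent with a cross-validated penalty path, stability-based gene
    selection through leave-one-out intersection of model supports, a
    mixed carry/interpolation imputation algorithm that turns irregular
    short expression series into complete series on a reduced time grid,
    triangular Global Alignment Kernel distances with partition-around-
    medoids clustering of patient trajectories, survival validation via
    Kaplan-Meier curves and log-rank tests, and a synthetic cohort
    generator with planted prognostic genes and trajectory clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    knitr,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
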