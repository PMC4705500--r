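Package: smlr
Title: Stacked Multivariate Linear Regression for Chromatographic
    Fingerprint Bioactivity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the bioactivity capacity of complex mixtures such as
    herbal extracts from high-dimensional HPLC-DAD chromatographic
    fingerprints (n samples much smaller than p time points).  Implements
    stacked multivariate linear regression (SMLR): a non-negative ridge
    meta-learner combining out-of-fold predictions of four linear base
    learners (principal component regression, partial least squares
    regression, orthogonal projections to latent structures, and the
    elastic net).  Includes the standard chemometric conditioning chain
    (airPLS baseline removal, correlation optimized warping, autoscaling),
    a bootstrap out-of-bag evaluation harness with one-way ANOVA model
    comparison, and a synthetic fingerprint generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    glmnet,
    pracma,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
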