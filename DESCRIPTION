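Package: firehsi
Title: Ensemble Habitat Suitability Models for Burned-Forest Nesting Specialists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and combines presence-background habitat suitability models
    for a post-wildfire nesting specialist on 30-m pixel landscapes.  Three
    model families share a common scoring contract (habitat suitability index
    in [0,1]): use-availability weighted logistic regression with all-subsets
    AICc selection, partitioned Mahalanobis D2 distance models built from
    principal components of nest-pixel covariates, and maximum-entropy
    density estimation with L1 regularization and a logistic output at
    prevalence 0.5.  Continuous scores are thresholded by maximizing
    predictive gain (the true skill statistic), classifications from eight
    models are combined into per-pixel ensemble counts, and diagnostics
    relate model agreement to multivariate environmental distance from the
    surveyed environmental space.  A synthetic-landscape generator with a
    known suitability truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
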