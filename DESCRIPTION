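Package: floatpool
Title: Species-Pool Null Models and Multimodel Occurrence Analysis for
    Freshwater Plant Functional Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse why an uncommon functional group (free-floating
    aquatic plants) is present or absent across freshwater lakes and ponds.
    Implements all-subsets logistic regression with AICc ranking and
    delta-AICc < 2 model averaging, threshold-based classification evaluation
    (optimal thresholds, confusion matrices, percent correctly classified,
    Cohen's kappa), a species-pool permutation null model for functional-group
    prevalence with an exact analytic oracle, correlation-matrix PCA of site
    environmental conditions, derived spatial predictors (neighbour counts,
    distance to nearest occupied water body, shoreline development index),
    and a synthetic-survey generator with spatially autocorrelated covariates
    and known logistic effects so that every stage is testable with known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
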