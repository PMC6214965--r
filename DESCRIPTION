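Package: spinepath
Title: Data-Driven Classification of 3D Spinal Curves and Surgical
    Outcome Prediction in Adolescent Idiopathic Scoliosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies three-dimensional spinal curves built from
    vertebral-centroid landmarks (T1-L5) in adolescent idiopathic
    scoliosis and predicts the two-year surgical outcome from treatment
    paths. Implements two-step isotropic curve normalization against a
    control-derived height template, K-means clustering with
    silhouette-based selection of the number of clusters at the
    pre-operative, early post-operative and two-year timepoints,
    fusion-level grouping from the instrumented vertebrae, treatment-path
    construction and path-to-outcome contingency analytics with a
    multinomial logistic regression likelihood-ratio test, clinical-style
    curve measurements with between-cluster comparisons, and a parametric
    synthetic-cohort generator with planted cluster structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
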