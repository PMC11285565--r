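Package: cpmr
Title: Connectome-Based Predictive Modeling with Consensus Edges and
    Network Segregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Connectome-based predictive modeling (CPM) of behavioural
    scores from functional connectivity matrices: covariate-adjusted
    edge-wise feature selection by partial correlation, summed-connectivity
    linear models under k-fold cross-validation, iteration ensembles with
    median-model selection, permutation-based significance with
    Benjamini-Hochberg correction, fold-by-iteration consensus-edge network
    summaries, node-level summed vectors, cross-group model transfer, and a
    weighted association-ratio network-segregation metric with group
    comparisons. Includes a synthetic-cohort generator that plants
    group-specific predictive edges with motion and age confound leakage so
    that every stage of the pipeline can be validated against a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
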