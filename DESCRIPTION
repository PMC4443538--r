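Package: capclust
Title: Time-Course Expression Clustering for Immobilization-Induced Joint
    Contracture Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a time-course microarray analysis
    workflow for gene expression in the rat posterior knee capsule during
    immobilization-induced joint contracture. Provides detection-call and
    expression-floor filtering, replicate medians and log2-ratio profiles,
    signed fold-change binning with direction summaries, Bayesian model-based
    agglomerative clustering of expression trajectories under a conjugate
    polynomial regression model (a working re-implementation of the CAGED
    clustering engine), cluster-center selection and trend classification,
    sham versus immobilized probe-set comparison with gene collapse, local
    hypergeometric/EASE over-representation analysis against GMT gene sets
    with per-cluster cross-tabulation, and Kruskal-Wallis scoring of
    two-examiner immunohistochemistry field counts. A synthetic-data module
    generates expression datasets with planted trajectory clusters and IHC
    count tables so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    fgsea,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
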