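Package: triSurv
Title: Two-Way Co-Clustering and Survival Prognosis for Radiomic Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Composite prognostic pipeline for censored survival prediction
    from high-dimensional radiomic feature tables. Implements
    reproducibility (intraclass correlation) and redundancy (Pearson)
    feature selection, orthogonality-constrained non-negative matrix
    tri-factorization that co-clusters patients and features and yields
    low-dimensional meta-features, Kaplan-Meier / log-rank risk
    stratification, and Cox, Lasso-Cox and random survival forest
    prediction under repeated cross-validation, together with K-means,
    PCA and clinical-variable baselines and a synthetic cohort generator
    with cluster-linked censored survival for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    glmnet,
    ranger,
    pracma,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
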