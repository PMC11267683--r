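Package: nanoptml
Title: Information-Fusion Perturbation-Theory Machine Learning for
    Nanoparticle-Drug Delivery Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building read-across classification models of
    nanoparticle-drug delivery systems from heterogeneous preclinical assay
    tables. Observed activity values are binarized by per-endpoint cutoffs and
    desirability signs, label-conditioned moving averages turn molecular and
    nanoparticle descriptors into perturbation-theory deviation features, and
    drug and nanoparticle assays are fused pairwise into a single labelled case
    table with group-frequency reference priors. Includes a classifier suite
    (decision tree, linear discriminant analysis, k-nearest neighbours, random
    forest, gradient boosting) with sensitivity/specificity/MCC/AUROC reporting,
    decision-tree family summaries, combinatorial prediction-grid simulation
    with binned probability heatmaps, and a synthetic-data generator with a
    planted logistic signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rpart,
    MASS,
    class,
    randomForest,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
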