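Package: adrnet
Title: Drug-to-Drug Network Features for Adverse Drug Reaction Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a weighted drug-to-drug network by projecting a binary
    drug-by-ADR (adverse drug reaction) incidence matrix onto drugs, with
    edge weights counting shared ADRs. Extracts ten per-drug network
    centrality features (degree, weighted degree, eigenvector, closeness,
    clustering coefficient, betweenness, authority, hub, triangles and
    weighted PageRank), concatenates them to PCA-reduced one-hot drug
    features, and evaluates per-ADR binary classifiers under SMOTE-balanced
    10-fold cross-validation with AUROC reporting and logistic-regression
    Wald p-value feature importance. Includes a synthetic-data generator
    with a planted latent-mechanism structure so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    rpart,
    ranger,
    xgboost,
    e1071,
    class,
    nnet
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
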