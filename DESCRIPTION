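Package: phew2p2v
Title: Phenome-Wide Incidence Risk Prediction with Weighted Patient Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for phenome-wide incidence-risk prediction from coded
    longitudinal health records. Maps ICD-9 diagnosis codes to phecodes with
    exclusion-range aware case/control/excluded status, builds per-admission
    medical-concept sequences, trains skip-gram concept embeddings with a
    deterministic negative-sampling trainer, summarises each patient's past
    records as a phenotype-tailored weighted vector (weights proportional to
    squared concept-phenotype cosine similarity), and scores incidence risk as
    the cosine similarity between the patient vector and the phenotype vector.
    Includes count-matrix baselines (L1-regularised logistic regression, random
    forest, gradient boosted trees), rank-based evaluation metrics (AUC-ROC,
    average precision, maximum F1), and a correlated-binary cohort simulator
    with a logistic outcome for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    glmnet,
    ranger,
    xgboost,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
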