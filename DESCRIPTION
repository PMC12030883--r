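Package: respiscreen
Title: Structural Alerts and Consensus Machine Learning for Respiratory
    Toxicity Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to flag chemicals as potential respiratory irritants or
    respiratory sensitizers. Ships the published libraries of 13 irritation
    and 18 sensitization structural alerts with a substructure profiler,
    a data-driven alert miner (fragment enumeration with precision-ranked
    greedy rule selection), consensus machine-learning classifiers over
    configurable fingerprint and physicochemical featurizers with a
    prediction-disagreement (CONS-STD) applicability domain, and an
    integrated confidence-scoring scheme that combines alert and model
    calls for hazard screening of arbitrary chemical lists. Includes a
    synthetic-data generator that plants alert substructures at controlled
    noise rates so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), ChemmineR
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineOB,
    randomForest,
    xgboost,
    glmnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Cheminformatics, Classification, StructuralPrediction
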