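Package: cuttleselect
Title: Hybrid Cuttlefish-Algorithm and Simulated-Annealing Wrapper Feature
    Selection for Clinical Tabular Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Wrapper feature selection for clinical tabular classification
    using a hybrid of the cuttlefish optimization algorithm (CFA) and
    simulated annealing (SA). Candidate feature subsets are encoded as
    bounded continuous position vectors, decoded to binary masks by
    thresholding, and scored by cross-validated classifier accuracy with an
    optional parsimony penalty. Includes the full CFA population machinery
    (four groups, six reflection/visibility cases), a Metropolis annealer
    with geometric cooling, an exhaustive subset-search oracle for small
    dimension, a ground-truth-bearing synthetic data generator, CSV/ARFF
    readers for UCI-style clinical data, and standard evaluation metrics
    (confusion matrix, accuracy, precision, recall, F1, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    class,
    e1071,
    rpart,
    randomForest,
    xgboost,
    foreign
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
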