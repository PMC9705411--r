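Package: methclass
Title: Methylation-Array Tumor Class Discovery and Calibrated Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for DNA methylation array (450k/EPIC beta value) tumor
    classification: probe and sample quality filtering, platform merging,
    variance-based CpG selection, unsupervised class discovery by t-SNE
    embedding and DBSCAN density clustering with a downsampling stability
    statistic, supervised classification (SVM and random forest) under a
    class-balanced multinomial cross-entropy grid search with an explicit
    "Unknown" outlier class, ridge-multinomial score calibration, and an
    evaluation protocol (outlier-detection sensitivity and specificity,
    per-category specificity, conditional accuracy, ROC/AUC). Includes a
    seeded synthetic methylation-cohort simulator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
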