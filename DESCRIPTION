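Package: noduleclick
Title: Click-Seeded Lung-Nodule Segmentation and Imbalance-Robust
    Invasiveness Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated segmentation of lung nodules on 2-D CT slices
    from a single user click: an adaptive Hounsfield-unit threshold
    calibrated by two regressions, 8-connected seeded region growing
    constrained to the lung, and a 3x3 erode / noise-removal / dilate
    morphology chain, with a candidate-fusion fallback rule when the
    threshold path returns nothing. Includes a reproducible radiomics-lite
    feature extractor, four feature-ranking methods, and BEED, a boosting
    ensemble built by equalized down-sampling of the majority class with
    AUC min-max member weighting and weighted voting, for classifying
    nodule invasiveness on heavily imbalanced data. Synthetic CT phantoms
    and imbalanced feature tables make the full pipeline testable without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    caret,
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    png,
    pROC,
    purrr,
    randomForest,
    rlang,
    RNifti,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
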