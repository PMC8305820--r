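Package: sonoradiomics
Title: Ultrasound Radiomics Texture Pipeline for Renal Parenchyma Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Masked-ROI radiomics for 2-D grayscale ultrasound: extraction of a
    180-dimensional texture signature per slice (14 first-order, 9 gray-level
    co-occurrence matrix and 13 gray-level run-length matrix features on the
    original image and on four non-decimated wavelet sub-bands), L1-penalized
    logistic regression with cross-validated binomial deviance for feature
    selection, and four-classifier evaluation (logistic regression, SVM,
    random forest, KNN) with slice-to-patient probability aggregation and ROC
    analysis. Includes a synthetic speckle-phantom cohort generator with
    annular parenchyma masks for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    png,
    tiff,
    jsonlite,
    glmnet,
    e1071,
    randomForest,
    class,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
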