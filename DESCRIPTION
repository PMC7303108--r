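Package: histotcm
Title: Tissue-Component Mapping and Texture-Based Grading of H&E Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and grades prostate cancer on whole-mount H&E
    histology tiles. Converts RGB images into three-class tissue-component
    maps (nuclei, lumina, other) by color deconvolution with per-slide
    adaptive Otsu thresholding, lumen color thresholds and red-blood-cell
    suppression; computes a fixed 156-element first-order/GLCM/GLRLM
    texture descriptor per region of interest; selects features by
    backward elimination ranked on leave-one-patient-out AUC of a Fisher
    linear discriminant; trains Fisher, logistic and SVM classifiers with
    class balancing; and evaluates with patient-stratified
    cross-validation, pooled ROC curves, per-tissue-type error rates and
    whole-slide label maps. Ships a seeded synthetic H&E slide generator
    with known ground-truth masks so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    tools,
    e1071,
    glmnet,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
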