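Package: mammopipe
Title: Mammography Image Classification with Gated Attention Fusion and
    Harris Hawks Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for multi-class classification of
    mammography-like grayscale images. Implements the full chain of
    min-max normalization, contrast-limited adaptive histogram
    equalization (CLAHE), Gaussian denoising, Otsu breast-region
    segmentation, seeded geometric augmentation and SMOTE oversampling;
    a miniature multi-axis (window + grid) self-attention transformer
    feature extractor trained from scratch; a gated attention fusion
    module (GAFM) combining multi-scale features through learnable
    logistic gates; binary Harris Hawks optimization (HHO) wrapper
    feature selection with cross-validated classifier-accuracy fitness;
    gradient-boosted classification; and a leakage-guarded stratified
    cross-validation protocol with a full metric suite (MCC, Cohen's
    kappa, macro one-vs-rest AUC, McNemar and paired t tests). A seeded
    synthetic-data generator provides mammogram-like images and planted
    feature matrices so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    png,
    EBImage,
    xgboost,
    glmnet,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
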