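Package: StainFOS
Title: Dual-Channel Stain Texture Features for Prostate Tissue Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Patch-based feature engineering for Hematoxylin and Eosin (H&E)
    histology images. Images are gamma corrected, tiled into non-overlapping
    64x64 patches and separated into Hematoxylin and Eosin concentration
    channels by Beer-Lambert colour deconvolution. Six first-order-statistic
    radiomic features are computed per channel, reduced by recursive feature
    elimination with a gradient-boosting baseline followed by one-way ANOVA
    eta-squared validation, and classified (benign versus malignant, low
    versus high grade) by classical models and a dual-channel bidirectional
    LSTM. Includes a seeded synthetic H&E tissue generator with known
    ground-truth stain concentrations, confusion-matrix and ROC/AUC
    evaluation, and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    EBImage,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    pROC,
    knitr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Preprocessing
RoxygenNote: 7.3.3
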