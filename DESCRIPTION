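Package: specorigin
Title: Spectral Origin Classification with Channel-Attention 1D Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for geographical-origin classification of fruit from
    reflectance spectra. Implements an efficient-channel-attention (ECA)
    enhanced one-dimensional convolutional network (ECNN-1D) together with
    plain CNN-1D, VGG-1D and ResNet-1D baselines, trained from scratch with
    AdamW, early stopping and multi-seed aggregation. Includes chemometric
    spectral preprocessing (Savitzky-Golay smoothing, standard normal
    variate, multiplicative scatter correction), PCA and UMAP feature
    reduction, stratified spectral-level splitting, classical baselines
    (LDA, KNN, and random forest / SVM via scikit-learn when available), a
    synthetic three-class reflectance generator for the Vis-NIR and SWIR
    band regimes, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    FNN,
    uwot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
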