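Package: cellchannel
Title: Label-Free Immune Cell Image Classification with Synthetic Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A testable re-implementation of a label-free immune-cell
    classification pipeline for multi-channel microscopy. Provides a
    synthetic field generator with per-cell ground truth emulating mixed
    LMPP / pro-B dishes imaged in phase-contrast-like, transmitted-light
    and fluorescence-marker channels; watershed-based single-cell
    segmentation (Otsu threshold, morphological cleaning, distance
    transform and marker-seeded region growing); per-cell cropping with
    flat-field correction of the marker channel; marker gating through a
    two-component Gaussian mixture with an unused low-confidence band;
    a convolutional neural network and a cell-size support vector machine
    classifier; and dish-level cross-validated ROC/AUC evaluation over
    grids of channel configurations, focal offsets, training-set sizes
    and initialisation seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    S4Vectors,
    e1071,
    Rcpp,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Classification, Software
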