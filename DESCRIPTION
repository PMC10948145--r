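Package: apodetect
Title: Spatiotemporal Detection of Apoptotic Cell Death in Live-Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects apoptotic events in single-channel timelapse microscopy by
    a region-proposal, temporal-clip classification, non-maximum suppression and
    centroid-tracking pipeline built around a convolutional-attention (Conv-
    Transformer) sequence classifier. Includes readers and writers for TIFF and
    HDF5 movies and CSV annotations, quantile-based 8-bit normalization, maximum
    intensity projection, a ground-truthed synthetic movie generator for in vitro
    (nuclear shrinkage and condensation) and in vivo (blebbing and fragmentation)
    phenotypes, training-set assembly with 2D augmentation and hard-negative
    mining, 3D rotation augmentation of volumetric event sequences, detection
    evaluation (TPR/FPR, nearest-neighbour distances, temporal offsets,
    cumulative-curve correlation, AOGM-based tracking accuracy, video quality
    score) and four-parameter log-logistic dose-response fitting with EC50 and
    Hill-slope estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    rhdf5,
    EBImage,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
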