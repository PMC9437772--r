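Package: fetalmask
Title: Automated Fetal Brain Masking and Preprocessing for Fetal fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automated extraction of the fetal brain from resting-state
    functional MRI time series, and the surrounding preprocessing pipeline.
    A 2D-slice U-Net, implemented from scratch with Armadillo-backed
    convolution kernels, predicts a per-voxel brain probability for every
    timepoint of a 4D acquisition; probability maps are thresholded,
    cluster-filtered, and carried back to native space. The package also
    provides grid standardization (resampling and zero-padding onto the
    network grid), rigid frame-to-frame realignment with framewise
    displacement censoring, linear normalization to a template with
    Gaussian smoothing, segmentation evaluation metrics (Dice, Jaccard,
    Hausdorff surface distance, sensitivity, specificity), and a synthetic
    fetal-fMRI phantom generator with ground-truth masks and motion so the
    whole system can be trained and validated without scanner data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
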