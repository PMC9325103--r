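Package: orbitseg
Title: Extraocular Muscle Segmentation and Morphometry on Orbital CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fully automated segmentation of the eight extraocular rectus-muscle
    classes on coronal CT slices with a patch-based 2D U-net, and measurement of
    per-muscle thickness and maximum cross-sectional area from the predicted
    multiclass masks. Provides Hounsfield-unit preprocessing (isometric spline
    resampling, display windowing, balanced patch sampling, flip-free
    augmentation), a suite of segmentation losses (weighted cross-entropy, Dice,
    IOU, Focal-Tversky, boundary loss on signed distance maps, and compounds),
    CPU training of the U-net with Adam and k-fold cross-validation,
    sliding-window majority-vote inference, minimum-area rotated-rectangle
    morphometry, a Dice/IOU and MAE/MAPE evaluation harness with three-region
    analysis and noise-robustness protocol, and a synthetic orbital-phantom
    generator with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
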