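Package: noisystudent
Title: Noisy-Student Semi-Supervised Lesion Detection and Segmentation on
    Synthetic Head Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a noisy-student self-training framework for lesion
    detection and segmentation at desk scale: a seeded generator of head-CT-like
    synthetic examinations with per-pixel lesion masks and controllable
    inter-institution domain shift; a small trainable dual-branch patch network
    with classification and segmentation heads and masked (tri-state) pixel
    losses; ranked pseudo-labeling with a percentile ranker and pixel confidence
    thresholds; mixed-minibatch student training with contrast and geometric
    noise; image-label and pixel-label Oracle benchmark modes; examination- and
    pixel-level metrics (ROC AUC, Dice, average precision, operating points);
    and paired-bootstrap model-comparison statistics with normality checks,
    Z-derived p-values and percentile confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
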