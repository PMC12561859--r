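Package: periomet
Title: Automated Periocular Landmark Measurement from Iris and Eyebrow
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective, calibrated measurement of periocular
    anatomy in ptosis assessment. Provides a synthetic periocular scene
    generator with pixel-exact iris and eyebrow masks and analytic
    landmark ground truth; a compact U-Net-style binary segmentation
    network trained natively in R (with saliency and Grad-CAM
    inspection and CPU latency benchmarking); geometric recovery of the
    corneal outline from a lid-occluded iris mask via a minimum
    enclosing circle, 11 mm corneal-diameter calibration, and derivation
    of seven landmarks (MRD1, MRD2, and eyebrow heights at the medial
    brow end, medial limbus, pupil center, lateral limbus, and lateral
    brow end); and the matching evaluation suite (pixel confusion
    metrics, IoU, F1, per-landmark RMSE and MAPE reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
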