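Package: adapthsi
Title: Adaptive Auto-Encoder Learning for Tumor Detection in Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pixel-wise tumor detection in hyperspectral reflectance cubes with a
    sparse auto-encoder feature learner and softmax classifier, adaptive
    re-weighting of misclassified training pixels (sensitivity- or
    specificity-focused), retraining on the re-weighted cubes, and morphological
    refinement of the detected mask. Includes white/dark reference reflectance
    calibration, readers and writers for ENVI, TIFF-stack and native array-bundle
    cubes, a synthetic hyperspectral phantom generator with known ground-truth
    masks, and a leave-one-out cross-validation driver with hidden-dimension
    tuning and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
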