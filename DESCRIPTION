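Package: halfcontour
Title: Half-Contour Shape Features for Breast Ultrasound Tumor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for morphologic analysis of breast tumors in B-mode
    ultrasound images affected by posterior acoustic shadowing (PAS).
    Implements per-column adaptive thresholding segmentation, Moore-neighbor
    contour tracing, extraction of the upper half contour between the
    leftmost and rightmost tumor pixels, and six contour shape features:
    tumor circularity (TC), mean and standard deviation of the normalized
    radial length (NRL), area ratio (AR), roughness index (RI), and the
    standard deviation of degree (SDD) vertex-angle irregularity statistic.
    Includes a seeded synthetic speckle phantom generator with controllable
    boundary spiculation and a posterior acoustic shadow artifact, plus
    ROC/AUC, Youden-threshold confusion metrics, and Welch t-test evaluation
    of feature discrimination between benign-like and malignant-like lesions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
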