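Package: shredvision
Title: Tobacco Shred Image Binarization, Segmentation and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end machine-vision pipeline for classifying the four
    component types of cigarette filler (expanded tobacco silk, cut stem,
    tobacco silk and reconstituted tobacco shred) from single-shred images
    on a bright background. Implements block-threshold binarization with a
    statistically calibrated standard-deviation gate (per-block Otsu inside
    gated-in blocks), kernel-density first-trough calibration of the gate,
    contour screening with square region-of-interest cropping, a
    configurable multi-scale residual network family (stage-3/stage-4
    feature fusion) with a clamped focal loss, equally weighted multiclass
    evaluation metrics, and a seeded synthetic-scene generator with
    per-pixel ground truth so every stage is testable without proprietary
    image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
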