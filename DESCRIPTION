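Package: snagdetect
Title: Multi-Scale Detection of Standing Dead Trees in UAV RGB Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects standing dead trees (snags) in aerial RGB image tiles
    with a two-stage detector built on a hierarchical shifted-window
    attention backbone, a balanced feature pyramid with non-local
    refinement, and dynamic training (adaptive IoU assignment threshold
    and adaptive smooth-L1 transition point).  Includes orthomosaic
    tiling, Labelme-to-COCO annotation conversion, geometry-preserving
    augmentation, a synthetic forest-scene generator for desk-scale
    experiments, and a COCO-style average-precision evaluation suite with
    size-stratified metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
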