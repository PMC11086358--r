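Package: segfuse
Title: Ensemble Fusion of Binary Segmentation Maps for Multi-Class
    Surgical Scene Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses per-class binary semantic-segmentation probability maps
    into a single multi-class label map with four ensemble operators
    (pixel-wise, weighted pixel-wise, region-based via connected-component
    majority vote, and weighted region-based), evaluates segmentations with
    image-level and class-level Jaccard and Dice scores, and provides the
    surrounding data-preparation steps: boundary-polygon rasterization and
    mask merging, per-class binarization, label-constrained random-crop
    augmentation, and video-grouped cross-validation splitting. A synthetic
    generator renders tubular anatomy-like scenes and simulates noisy,
    miscalibrated binary-network outputs so the whole pipeline is testable
    without a surgical dataset or trained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
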