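Package: MVLeafSeg
Title: Zero-Shot 3D Leaf Instance Segmentation from Multi-View Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Lifts per-view 2D leaf instance masks onto a reconstructed 3D
    point cloud and fuses them into a single 3D instance segmentation.
    Provides the three-stage mask post-filter (saturation, overlap, shape),
    calibrated pinhole projection with depth-consistency gating, a
    viewpoint/depth confidence score, incremental confidence-driven label
    merging, a turntable point-cloud preprocessing chain (RANSAC 3D circle
    fit for scale calibration, pass-through/RGB/statistical filters, voxel
    downsampling), the full point-level, object-level and count-agreement
    evaluation suite, and a synthetic turntable scene generator with a
    z-buffer point-splat renderer that emulates the camera + SfM/MVS +
    segmenter front end for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
biocViews: Segmentation, Visualization, Preprocessing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
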