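Package: fundusreg
Title: Bifurcation-Based Retinal Fundus Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature-based registration of colour fundus photograph pairs
    using vascular bifurcations as landmarks. Provides coarse vessel
    segmentation by a cumulative-distribution-function threshold combined
    with a normalized gray-level co-occurrence statistic, Zhang-Suen
    skeletonization, hit-or-miss bifurcation detection, gradient-orientation
    (HOG) descriptors with cross-checked second-nearest-neighbour matching,
    distance-constrained RANSAC estimation of similarity or affine
    transforms, Laplacian-pyramid mosaicking, a control-point registration
    error evaluation protocol with success curves and AUC, and a seeded
    synthetic fundus-pair generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
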