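Package: leafcal
Title: 3D Calibration of Leaf Hyperspectral Imagery Using Depth Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Removes leaf tilt-angle and orientation effects from indoor
    hyperspectral plant imagery. Fuses pushbroom hyperspectral cubes with
    depth-camera point clouds through a direct-linear-transformation
    projection model (with optional third-degree Chebyshev residual
    refinement), estimates per-pixel leaf tilt angle and orientation from
    local surface normals, models the angular response of NDVI with support
    vector regression under venetian-blinds cross-validation, and divides
    pixel NDVI by the predicted ratio so curved or tilted leaves are
    calibrated to the flat-leaf standard. Includes white/dark reflectance
    calibration, red-edge leaf segmentation, a synthetic scene generator
    (checkerboard calibration targets, tilted and arched leaf scenes,
    rotation-protocol datasets), and an evaluation toolkit (kernel density
    curves, patch means with paired t-tests, balanced two-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    e1071,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
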