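Package: pigback
Title: Non-Contact Pig Weight Estimation and Back Morphometrics from 3D Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating sow body weight and back body measurements
    from overhead depth-camera point clouds. Provides PLY point-cloud input
    and output, voxel-grid down-sampling, K-means scene segmentation with
    elbow-based selection of the cluster count, density-based removal of the
    head and tail, oriented-bounding-box pose normalization, shoulder,
    abdominal and hip width extraction by three-section slicing, and a
    multi-head-attention convolutional regressor (MACNN) that predicts body
    weight from the back point cloud, optionally using per-point RGB colour
    as an additional feature. A parametric synthetic-scene generator with
    per-point ground-truth labels supports end-to-end testing without farm
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
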