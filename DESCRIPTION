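Package: autoknee
Title: Automated CT-to-Custom Total Knee Replacement Design Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An automated pipeline that turns an axial CT slice stack of a
    knee into patient-specific total knee replacement implant geometry.
    Slices are classified into anatomical regions, cropped to a fixed
    region of interest around the knee, and segmented per bone; per-slice
    bone contours are assembled into 3-D contour stacks split at an
    automatically detected tibia-femur transition; per-bone statistical
    shape models are rigidly aligned (iterative closest point) and morphed
    over a limited number of principal components to predict 3-D bone
    surfaces; generic femoral components and tibial plates are generated
    from the predictions by deterministic geometric operations; and implant
    fit is scored by surface root-mean-squared error and maximum
    over/underhang (directed Hausdorff distance) against ground-truth bone
    models. A parametric synthetic knee-phantom generator provides
    corresponded mesh populations and CT-like volumes with full ground
    truth so the whole pipeline can be trained and evaluated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    nnet,
    EBImage,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
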