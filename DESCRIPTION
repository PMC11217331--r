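Package: canovol
Title: Canopy Volume Measurement from UAV Digital Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring orchard canopy volume from photogrammetric
    digital surface models (DSM). The pipeline partitions a georeferenced DSM
    into fixed-size square plots, classifies each pixel as ground or canopy
    with Otsu elevation-histogram thresholding or RANSAC ground-plane fitting,
    and integrates per-pixel canopy height over the segmented mask to obtain
    per-plot canopy volume. Also included: tree-height extraction around
    surveyed base positions, a voxelized point-cloud reference volume for
    validation against mobile laser scans, segmentation scores (mean IoU, mean
    pixel accuracy) and volume error metrics (RMSE, relative RMSE, MAPE), and
    a synthetic-orchard generator with analytically known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
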