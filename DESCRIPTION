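Package: tomocloud
Title: 3D Point-Cloud Reconstruction and Morphometrics for Micro-CT Slice Stacks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs volumetric and surface point-cloud 3D models from
    ordered stacks of 2D micro-CT slice images, either directly (every
    foreground voxel becomes a point) or after grey-window plus edge-detection
    segmentation (Roberts cross and six alternates), with anisotropic voxel
    spacing so models are volumetrically faithful. Includes Wavefront OBJ
    point-cloud export/import with label colours, morphometric reports
    (principal-axis dimensions, voxel-count volumes, percent-change and index
    tables across repeated scans), cloud-to-cloud nearest-neighbour distance
    fields and point-to-point ICP registration for deformation monitoring,
    and a parametric synthetic phantom generator (tapered ellipsoid body with
    planted cracks and pores, full ground truth) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
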