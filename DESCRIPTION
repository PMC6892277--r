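Package: placvasc
Title: Multiscale Quantification of Feto-Placental Vascular Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the density of the contrast-perfused
    feto-placental vascular tree across imaging scales. Implements reading and
    chunked processing of micro-CT TIFF slice stacks, histogram-midpoint
    segmentation of tissue and vessel, cord-insertion-centred normalised
    distance maps, topology-preserving 3D skeletonisation with per-voxel
    radius measurement and large-vessel exclusion, radial and block-level
    vascular density, histology particle analysis with vascular-fill quality
    control, and the accompanying rank-based statistics. Includes 3D and 2D
    phantom generators with voxel-exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    yaml,
    EBImage,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
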