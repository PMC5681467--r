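Package: tubuseg
Title: Blockwise Random-Forest Segmentation of Tubular Structures in 3D Micro-CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated segmentation of airway and blood-vessel walls in
    large 3D microfocus-CT volumes of wax-embedded lung tissue. Provides
    out-of-core processing of TIFF volumes as grids of cubic blocks with halo
    exchange and a JSON sidecar of global intensity properties; a slice-wise
    filter bank (Gaussian, neighbors, entropy, structure-tensor and Hessian
    eigenvalue features) feeding a random-forest voxel classifier trained from
    sparse manual labels; two-stage threshold refinement and connected-region
    or morphological noise removal; synthetic tube phantoms with ground truth
    for validation; and export of colorized overlays and binary STL surface
    meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    ranger,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
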