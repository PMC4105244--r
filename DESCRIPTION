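Package: seedscan
Title: Grain Size and Colour Phenotyping from Flatbed Scanner Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments individual cereal grains from flatbed-scanner images and
    measures per-grain size (area, perimeter, best-fit-ellipse length and width
    in millimetres) and device-independent CIELAB colour. Segmentation uses
    contour-preserving attribute morphology (max-tree openings, closings and
    elongation thinning), automated global thresholding from a bivariate
    grey-level/gradient histogram, and distance-transform watershed splitting of
    touching grains. Colour is calibrated by linear regression against a scanned
    24-swatch ColorChecker card, and an optional crease detector partitions
    colour measurements into crease and non-crease regions via a minimum-cost
    path along the grain's long axis. Includes deterministic synthetic-scene
    generators with pixel-exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jpeg,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
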