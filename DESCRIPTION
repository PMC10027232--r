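Package: phenocloud
Title: Field Crop Phenotyping from LiDAR Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable processing chain for extracting maize plant
    traits from field LiDAR point clouds: sphere-target scale calibration and
    direct linear transformation (DLT) image-to-cloud registration,
    statistical outlier removal and voxel-grid down-sampling, RANSAC soil
    plane fitting with scene leveling and ground removal, geometric plant
    instance segmentation, and per-plant trait extraction (plant height, leaf
    length, width, inclination and growth height). Includes a ground-truthed
    synthetic maize-canopy generator for end-to-end validation, evaluation
    statistics (coefficient of determination, root mean square error,
    relative errors) for manual-versus-system comparisons, and a bundled
    manual/LiDAR plant-height validation table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
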