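Package: urbancanopy
Title: Individual Tree Detection and Above-Ground Biomass Mapping from
    Multi-Scale LiDAR in Urban Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating urban above-ground biomass (AGB) from
    airborne laser scanning (ALS). Implements a two-stage individual tree
    detection algorithm for low pulse-density point clouds (3D density
    clustering into crowns and canopies, followed by allometrically
    thresholded radius clustering that splits merged canopies), crown
    structure metrics (maximum height, projected crown area from the 2D
    convex hull, equivalent crown radius), terrestrial-LiDAR-derived volume
    allometry fitted against quantitative structure model (QSM) tree tables,
    wood-density conversion of stem volume to AGB and carbon, per-hectare
    rasterization of biomass and tree density, and Monte Carlo propagation
    of QSM, crown-measurement and wood-density uncertainty. A synthetic
    urban-scene generator with known ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
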