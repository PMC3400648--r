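Package: mldcyto
Title: Cell Identification and Tracking with Nanoparticle Moving Light Displays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts multi-focal-plane fluorescence time-lapse movies of
    quantum-dot-labeled cells into binary point maps, identifies cells by
    seeded k-means clustering of the point sources, links cluster centroids
    through time, detects mitosis from the characteristic contraction and
    expansion of each cell's point cloud, and assembles lineage trees and
    motility statistics. Includes a ground-truthed synthetic movie simulator
    so every stage of the pipeline can be validated at desk scale, and an
    operational-range analysis that sweeps the intensity threshold to map
    the regime in which identification and localization are reliable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
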