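Package: orchardtraits
Title: Canopy Architectural Traits of Orchard Trees from UAV and LiDAR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts tree height and canopy crown volume for individual
    orchard trees from photogrammetric rasters (digital surface and terrain
    models) and from 3D point clouds. Implements canopy height models with
    two terrain variants (delivered terrain model, or terrain reconstructed
    by inverse-distance-weighted interpolation of sampled ground points),
    per-tree boundary delineation in three geometries (polygon, bounding
    box, minimum enclosing circle) with pyramid crown-volume formulas, and
    a point-cloud pipeline with tilt correction, statistical outlier
    filtering, extent-based single-tree segmentation, voxel-grid and
    tetrahedral convex-hull crown volumes. A synthetic-orchard generator
    with exact ground truth emulates view-angle-dependent surface sampling
    (nadir versus oblique) for validation, and a reporting module computes
    Pearson correlations with significance stars, linear fits, and
    distribution summaries against ground-reference measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    FNN,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
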