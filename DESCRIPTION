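Package: heifer3d
Title: Morphometric Analysis of 3D Body Scans of Growing Dairy Heifers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting morphological traits, body surface area and
    volume from watertight triangulated body meshes of cattle, predicting body
    weight from those traits with published allometric and linear equations,
    refitting prediction equations, scoring scan quality (including the "skirt"
    reconstruction artifact between the legs), reconstructing surfaces from
    oriented point clouds, and analysing longitudinal growth (interpolation,
    growth ratios, surface-to-volume dynamics). A parametric synthetic-heifer
    generator with closed-form ground truth makes every stage testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
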