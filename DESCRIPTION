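Package: conchmetrics
Title: Ornamentation and Surface-Complexity Metrics for Shell Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies the sculptural complexity of shelled animals
    (ammonites, gastropods, bivalves, echinoids) from triangle meshes of
    3D-scanned specimens.  Implements the ornamentation index OI = S/S' - 1
    computed from an ornamented mesh and a smooth reference model of the
    same conch geometry, together with the companion surface-complexity
    measures it is compared against: surface-to-volume ratio, rugosity
    (surface area over projected silhouette area), and the
    Bouligand-Minkowski multiscale fractal dimension obtained by voxel
    dilation.  Includes readers and writers for OBJ, PLY and STL meshes, a
    parametric generator of matched ornamented/smooth logarithmic-spiral
    conch pairs for testing and simulation, batch metric tables, and
    pairwise Pearson correlation reports with significance annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
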