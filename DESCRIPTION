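Package: collagraph
Title: Graph-Theoretic Quantification of 3D Cell-Mediated Collagen Remodeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds 3D cell-graphs from segmented nuclei in two-channel
    confocal image stacks, partitions the voxel grid with node- and
    edge-seeded discrete Voronoi diagrams, and quantifies collagen
    organization in the second-harmonic-generation channel. Provides the
    Collagen Alignment Index (CAI), computed from magnitude-weighted
    distributions of the angle between intensity-gradient vectors and
    cell-graph edges, and the Cell/Global Dissatisfaction Level (CDL/GDL),
    computed by minimum-norm projection of per-cell net gradient vectors
    onto incident cell-graph edges. Includes weighted two-sample
    Kolmogorov-Smirnov comparison of clipped angle distributions, SVD plus
    k-means phase clustering, and a seed-deterministic synthetic image
    generator with planted nuclei and oriented collagen stripe fields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
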