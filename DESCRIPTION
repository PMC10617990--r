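Package: foliametry
Title: Folial Morphometry and Phylogenetic Comparative Analysis of
    Cerebellar Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Contour-based morphometry of cerebellar histological
    sections (section area and length, multiscale curvature signatures,
    gyrus/sulcus/wall classification, folial width and perimeter,
    gyrification index), molecular-layer thickness estimation by
    Laplacian-potential streamlines and grey-profile boundary detection,
    and multivariate phylogenetic comparative statistics (Brownian
    motion, Ornstein-Uhlenbeck and early-burst model fitting with AICc
    ranking, phylogenetically conditioned covariance and partial
    correlations with edge-exclusion tests, phylogenetic PCA, bivariate
    and multivariate allometry, ancestral state estimation, and power
    simulations). Includes seeded synthetic-data generators for folded
    contours, layered section images, ultrametric trees and trait
    matrices, so the whole pipeline can be exercised end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    pracma,
    randomForest,
    EBImage,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
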