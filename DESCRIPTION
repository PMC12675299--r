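Package: plaquemap
Title: Spatial Analysis of Amyloid-Plaque-Associated Microglia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for imaging-based spatial transcriptomics (MERFISH-style)
    analysis of microglia around amyloid plaques: cell quality filters and
    volume-aware log normalization, centroid-to-plaque-edge distance
    classification of plaque-associated versus distal cells within a traced
    region, Wilcoxon rank-sum marker detection with expression-fraction and
    fold-change filters, control-gene-matched module scoring with
    lymphoid/interferon signature categorization of clusters, and a
    reference-fold-change classifier of PU.1 nuclear-intensity states.
    Includes a seeded negative-binomial simulator of MERFISH-like tissue with
    ground truth, so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
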