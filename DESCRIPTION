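Package: ribbonquant
Title: Quantification of Ribbon-Synapse Structure and Activity in Cochlear Hair Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An image-analysis and electrophysiology quantification pipeline for
    activity-dependent structural plasticity at inner-hair-cell ribbon synapses.
    Provides 2D-STED cluster-area analysis (Gaussian blur, Kapur maximum-entropy
    thresholding, watershed splitting, moment-based ellipse fitting), parameterized
    3D puncta reconstruction with local background subtraction and quality
    filtering, nearest-neighbour surface-distance classification of ribbons as
    synaptically engaged or cytoplasmic with per-cell normalization, calcium
    (GCaMP) and current-clamp voltage trace event analysis, patterned optogenetic
    pulse-train schedules, and the associated statistical comparisons. A synthetic
    data generator with ground-truth manifests stands in for raw microscopy and
    electrophysiology recordings so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
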