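Package: CometKit
Title: Automated Detection, Characterization and Classification of
    Comet-Assay Images
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A fully automated analysis pipeline for single-cell gel
    electrophoresis (comet assay) fluorescence micrographs. Detects an
    unconstrained number of comets at arbitrary positions via first-valley
    adaptive histogram thresholding, separates overlapping comets with a
    distance-transform/wavelet/watershed cascade validated by Fourier shape
    descriptors, characterizes every comet (head radius, tail length and
    distance, DNA fractions, extent moment, Olive moment and moment of
    inertia), and classifies damage states (normal, necrosis, apoptosis)
    from histogram-of-oriented-gradients features. Includes a seeded
    synthetic-scene generator with full ground truth and region- and
    centroid-based evaluation metrics, so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    e1071,
    nnet,
    rpart,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: CellBiology, Software, Visualization, Classification
RoxygenNote: 7.3.3
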