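Package: geromorph
Title: Local Brain Age from Cortical Surface Morphometry with a Graph U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vertex-level local brain age (LBA) estimation on cortical surface
    meshes. Implements nested icosphere atlas hierarchies with receptive-field
    pooling between resolutions, a three-resolution graph U-Net (graph
    convolutions, batch normalisation, skip connections) trained with a
    vertex-wise mean absolute error loss, medial-wall removal and iterative
    neighbourhood smoothing of predicted age maps, semi-global bias correction
    of brain-age gaps, integrated-gradients feature attribution, and
    region-level group statistics (t-tests with Benjamini-Hochberg correction,
    chronological-age-binned sex bootstraps, cognition regressions). A
    synthetic cortical-cohort simulator with known ground truth makes the full
    pipeline testable without MRI data. Readers and writers for FreeSurfer
    binary surface, curv and annot files are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
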