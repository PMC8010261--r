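Package: neurocascade
Title: Connectome Features, Separable-Convolution Pruning, and Cascaded
    Multimodal 3D-CNN Classification for Alzheimer's Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for quantifying Alzheimer's-related
    cognitive status from multimodal brain imaging. Builds functional
    (BOLD correlation) and structural (fractional-anisotropy) brain
    networks and extracts weighted graph-theory features (degree, local
    efficiency, betweenness centrality) with Welch t-test feature
    selection; prices standard, depthwise-separable and channel-pruned
    convolution layers in closed form; performs APoZ-based channel
    pruning of depthwise-separable units with mask-then-materialize
    equivalence; trains a cascaded multimodal 3D convolutional
    classifier (per-block local nets, per-location fusion nets, final
    combiner) with shift augmentation and stratified cross-validation;
    and maps discriminative regions by occlusion. All stages are
    exercisable end-to-end on a bundled synthetic-cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    RNifti,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
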