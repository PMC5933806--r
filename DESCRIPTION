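Package: navrsa
Title: Navigational-Affordance Representational Similarity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic re-implementation of a
    representational-similarity-analysis (RSA) pipeline for studying how
    navigational affordances -- the directions in which an observer could
    walk through a depicted scene -- are encoded in visual responses.
    Provides generators for parametric indoor scenes, rater path maps,
    voxel-pattern cohorts with planted representational geometry, and
    labelled unit-activation sets; a 180-bin angular affordance histogram
    with penalized discrete-cosine smoothing; squared-Euclidean
    representational dissimilarity matrices (RDMs) with the normalization
    conventions of condition-rich fMRI designs; Spearman RSA with bootstrap
    subsampling, permutation tests, Bonferroni correction and noise
    ceilings; multiple-regression RSA with commonality variance
    partitioning; a small configurable feedforward convolutional network
    together with in-silico experiments on it (stimulus filtering, slice
    occlusion, occlusion-based receptive-field mapping, unit clustering)
    and navigability classification with unit-resampling nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rtsne,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
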