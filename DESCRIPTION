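Package: ictfce
Title: Incremental Cluster Threshold-Free Cluster Enhancement for Connectome and Voxel Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-free cluster enhancement (TFCE) for functional-connectivity
    (ROI-by-ROI) statistic matrices and 3D voxel statistic maps. Implements the
    incremental-cluster TFCE algorithm, which builds supra-threshold clusters once
    from the highest threshold downward and retrieves per-edge TFCE values from a
    node-indexed accumulation structure, decoupling runtime from the integration
    step size; a brute-force discretized TFCE that recomputes connected components
    at every threshold (the correctness oracle); an exact, discretization-free TFCE
    computed piecewise between consecutive sorted statistics with a closed-form
    integral; and a graph transformation that maps voxel volumes onto the same
    edge-based machinery. A max-statistic permutation layer provides
    familywise-error-corrected p-values and empirical power estimation, and
    generators produce synthetic statistic matrices, group datasets with planted
    effects, and voxel volumes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
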