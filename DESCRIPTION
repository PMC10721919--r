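Package: papillar
Title: Geometric and Topological Analysis of Tongue Papillae in 3D Surface Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying the microscopic 3D shape of human tongue
    papillae from triangulated surface scans. Generates synthetic tongue-like
    surfaces with planted fungiform (dome-shaped) and filiform (crown-shaped)
    papillae and participant-level covariates; extracts candidate papilla
    segments by RANSAC base-plane fitting and local-maximum detection; computes
    baseline (height, radius), discrete-curvature (angle-deficit Gaussian and
    cotangent mean curvature with mixed Voronoi areas) and topological
    (Vietoris-Rips persistent homology summaries: short bars, persistent
    entropy, landscape/image/Wasserstein/bottleneck amplitudes) features; and
    runs interpretable classification studies (papilla type, gender, age group,
    participant identity) with balanced accuracy over repeated stratified
    splits and leave-one-group-out folds, plus permutation feature importance
    and whole-surface papillae mapping ("tongue prints").
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    glmnet,
    igraph,
    withr,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
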