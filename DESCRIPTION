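Package: dermafiber
Title: Dermal Elastin Fiber Architecture and Skin Firmness by Finite Element Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking the three-dimensional architecture of the dermal
    elastin fiber network to macroscopic skin firmness. Provides a synthetic
    fiber-network generator with donor-age presets, a 3D image-processing
    pipeline (median filtering, thresholding, binary morphology, surface
    smoothing, skeletonization and distance-transform diameter estimation),
    graph-based architecture metrics (fiber count, mean diameter, elastin
    volume fraction, connected-component cluster statistics, vertical fiber
    proportion), a nonlinear finite-element model of unconfined dermal
    compression with a Saint Venant-Kirchhoff matrix and embedded
    Euler-Bernoulli beam fibers, and the cohort statistics (Welch t-tests,
    Pearson correlations, linear regressions) connecting architecture to
    normalized skin firmness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
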