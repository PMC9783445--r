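Package: osteoconv
Title: Bone Microanatomy Quantification and Phylogenetic Convergence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies long-bone microanatomy from three-dimensional voxel
    volumes (bone volume fraction, sphere-fitting local trabecular thickness,
    diaphyseal global compactness) and analyses such traits in a phylogenetic
    comparative framework: generalized least squares with maximum-likelihood
    Pagel's lambda and tip-height variance weights on possibly non-ultrametric
    timetrees, phylogenetic ANCOVA, body-mass imputation from cross-sectional
    area, fossil tip grafting and node recalibration, and a univariate C1
    convergence statistic with a Brownian-motion simulation null. Includes
    generators for synthetic timetrees, adaptive-regime trait evolution
    (Brownian motion and multi-optimum Ornstein-Uhlenbeck), and trabecular
    voxel phantoms of known bone fraction and strut thickness, so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
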