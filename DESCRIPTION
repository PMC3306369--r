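Package: paleomacro
Title: Macroevolutionary Analysis of Fossil Clades from Cladistic Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for macroevolutionary analysis of fossil clades from
    discrete character matrices and stratigraphic occurrence data: Fitch
    parsimony scoring with heuristic tree search (random-addition replicates
    and TBR branch swapping), Bremer decay indices, strict consensus and
    ensemble homoplasy indices; stratigraphic time-calibration of cladograms;
    ghost-lineage phylogenetic diversity curves; cladistic disparity via
    pairwise character dissimilarity, Cailliez-corrected principal
    coordinates, and rarefaction confidence intervals; and maximum-likelihood
    comparison of stasis, Brownian-motion, and Brownian-motion-with-trend
    models of continuous trait evolution with measurement error. Includes a
    synthetic-data generator emulating the statistical structure of such
    datasets so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
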