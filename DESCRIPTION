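Package: dockvar
Title: Docking-Based Interface Prediction and Structural Annotation of
    Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interface and hot-spot residues from
    rigid-body docking simulations when no complex structure is available,
    using normalized interface propensity (NIP) scores derived from the
    lowest-energy docking poses and distance-based extension of the
    predicted patches. Classifies residues and missense variants (nsSNPs)
    as core, interface or non-interacting surface from solvent
    accessibility and inter-atomic contacts, reconciles UniProt sequence
    numbering with structure numbering, and computes the enrichment
    statistics (observed/expected ratios, odds ratios with exact two-tailed
    p-values, sensitivity and precision against random baselines) used to
    characterize disease variants in protein interaction networks.
    Includes synthetic fixture generators for toy docking complexes and
    variant tables with planted location biases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
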