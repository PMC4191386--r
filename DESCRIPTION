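Package: ribodesign
Title: Complete RNA Inverse Folding and Thermodynamic Selection of
    Cis-Cleaving Hammerhead Ribozymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational design pipeline for cis-cleaving type III
    hammerhead ribozymes: complete, deterministic enumeration of RNA
    sequences whose minimum free energy structure equals a target
    (constraint propagation over IUPAC sequence space with provable
    unsatisfiability), ensemble-thermodynamic candidate scoring (positional
    entropy, ensemble defect, expected base-pair distance, structural
    diversity, Boltzmann probability of the target) through a pluggable
    thermodynamic engine (ViennaRNA Turner nearest-neighbour backend and a
    built-in exhaustive toy backend), constraint construction from multiple
    alignments, density-of-states screening for modular ribozyme placement,
    and first-order cleavage-kinetics fitting with measure/rate
    correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    minpack.lm,
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
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
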