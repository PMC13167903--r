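Package: ithsim
Title: Hallmark-Integrated Lattice Simulation of Intratumor Heterogeneity
    in Melanoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of superficially spreading melanoma on a
    two-dimensional lattice, integrating cancer hallmarks (proliferation,
    survival, genetic instability, antigenicity) mapped onto melanoma driver
    genes, immune-editing feedback through cytotoxic T lymphocyte recruitment,
    and BRAF-mutant cell motility. Includes analysis tooling for intratumor
    heterogeneity (similarity-matrix SVD entropy, mutation burden, clustered
    box-counting fractal dimension), tumor morphology (convexity, border
    fractal dimension), cross-pair correlation functions for spatial cell
    arrangements, four population sampling strategies with error evaluation,
    and reproducible experiment drivers including Morris elementary-effects
    sensitivity screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    mgcv,
    readr,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
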