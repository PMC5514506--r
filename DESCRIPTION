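Package: granusim
Title: Agent-Based Simulation of De Novo Anaerobic Sludge Granulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based model of de novo granulation in anaerobic
    digesters. Spherical acidogen and methanogen agents grow by Monod
    kinetics on glucose and acetate fields solved as pseudo-steady-state
    reaction-diffusion problems on a 2-D grid, divide, starve into an
    inert dead core, and are packed by shoving and adhesion mechanics.
    Includes a reactor-scale aggregation scenario, granule morphology and
    radial-stratification analysis, specific methanogenic activity, and a
    grid-search engine over bulk glucose and inoculum composition for
    methane yield.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
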