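Package: schoolsim
Title: Burst-and-Coast Fish School Simulation with Selective Neighbor Interactions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Event-driven simulation of burst-and-coast swimmers (rummy-nose
    tetra style) in a circular arena or an unbounded plane, built on
    data-driven pairwise attraction, alignment and wall-repulsion interaction
    functions. Supports topological (k-nearest), random and influence-based
    neighbor selection at every kick, group-level observables (cohesion,
    polarization, wall distance and orientation of the barycenter,
    counter-milling index), empirical-PDF comparison via the Hellinger
    distance, attraction cut-off sweeps with critical cut-off estimation, and
    a preprocessing pipeline for frame-wise tracked trajectories (pixel
    conversion, identity reassignment, rest filtering, sequence extraction,
    kick detection) together with a synthetic tracked-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
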