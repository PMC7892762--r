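Package: modlsm
Title: Modular Liquid State Machines with Hough-Transform Input Synapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Build and simulate liquid state machines (LSMs) whose reservoir is
    partitioned into internally recurrent modules wired into a directed acyclic
    graph. Provides retina-like image encoding (difference-of-Gaussians
    filtering and Poisson rate coding), input synapse maps that realize the
    line and circle Hough transforms in the firing rates of the first reservoir
    modules, generators for random, small-world, distance-dependent (metric)
    and modular reservoir topologies, a leaky integrate-and-fire network
    simulator with delayed typed synapses and an exactly equivalent
    divide-and-conquer modular scheduler, a linear support-vector readout on
    firing-rate features, synapse-ablation robustness sweeps, and float-operation
    cost accounting for monolithic versus modular execution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    e1071,
    dplyr,
    purrr,
    tibble,
    ggplot2,
    rlang,
    jsonlite,
    withr,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
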