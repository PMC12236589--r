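Package: gridnav
Title: Grid-Cell Path Integration, Hippocampal Recall, and Phase-Based Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis workbench for a hippocampal-entorhinal
    loop model of internally driven navigation. Generates synthetic foraging
    trajectories and ground-truth tuning maps (multi-scale triangular-lattice
    grid modules, spatially modulated sensory cells, speed and head-direction
    cells), trains a single recurrent network with auxiliary input and output
    nodes to path-integrate self-motion and autoassociate sensory patterns
    with grid codes under input masking, and identifies emergent
    place-cell-like hidden units. Includes an analytic planning stack on the
    grid-cell torus: shortest-wrap phase-difference decoding, multi-scale
    displacement combination with a contraction guarantee, Markov
    transition-matrix sequential planning, and greedy vector navigation, plus
    a learned planner subnetwork that drives the network with internally
    generated speed and head-direction commands. Analysis tools cover ratemap
    aggregation, nearest-neighbour population decoding, Skaggs spatial
    information, grid scores, recall queries, and PCA visualization of recall
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
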