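Package: moranamp
Title: Fixation Probabilities and Amplifiers of Selection for Moran
    Processes on Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Moran process on population-structure graphs
    under Birth-death (Bd), death-Birth (dB), and mixed delta-dB updating.
    Computes fixation probabilities of a single invading mutant exactly,
    by solving the full absorbing Markov chain over mutant configurations
    or symmetry-lumped chains for the Complete, Ring, Star, Complete
    Bipartite, and Fan families (reaching population sizes in the
    hundreds), and stochastically by seeded Monte Carlo simulation.
    Includes the well-mixed closed forms, the linear-interpolation
    baseline for mixed updating, upper bounds on death-Birth
    amplification, transience thresholds, implied-scale-of-fitness
    curves, amplifier classification, and reproducible experiment grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
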