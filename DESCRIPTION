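Package: msmflux
Title: Markov State Model Analysis of Ligand Translocation Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and validating Markov state models (MSMs) of
    ligand translocation from ensembles of short molecular-simulation
    trajectories. Covers the full analysis chain: featurization of raw
    coordinates into translocation metrics (center of mass, membrane tilt
    angle, group distances), time-lagged independent component analysis
    (tICA), k-means / mini-batch k-means state decomposition with
    least-counts adaptive-sampling seed selection, reversible
    maximum-likelihood MSM estimation with implied-timescale, VAMP2,
    bootstrap and Chapman-Kolmogorov validation, MSM-reweighted free-energy
    surfaces with minimax (minimum-energy-path) barrier extraction and
    barrier comparison, transition-path-theory committors, reactive fluxes
    and mean first passage times, a one-dimensional adaptive-biasing-force
    (ABF) potential-of-mean-force estimator, and a sphere-probe tunnel
    radius profiler for channel structures. Includes an overdamped Langevin
    simulator with analytic model potentials (double well, two-channel
    landscapes) so every estimator can be exercised against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    igraph,
    bio3d,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
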