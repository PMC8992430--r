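Package: neuremu
Title: Statistical Emulation and Surrogate-Assisted Optimization for Spiking-Neuron Simulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for replacing expensive biophysical neuron simulations with
    fast statistical emulators inside feature-based multi-objective model
    fitting. Provides a deterministic adaptive-exponential integrate-and-fire
    stand-in simulator with electrophysiology feature extraction and structural
    missingness, a family of emulators (Gaussian-process regression with ARD
    squared-exponential kernel, its limiting-linear-model variant, local
    approximate GP, greedy treed models, random-forest, neural-network and
    linear baselines) under one prediction contract, a two-stage
    classifier-plus-regressor pipeline for features that are undefined in some
    simulations, a genetic algorithm with four emulation strategies (full
    simulation, per-generation 80/20 split, whole-generation emulation with
    drift checks, and offspring screening), and emulator-based inference:
    predictive-interval coverage and Monte-Carlo Sobol sensitivity indices with
    standard-normal noise-factor negative controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lhs,
    randomForest,
    nnet,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
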