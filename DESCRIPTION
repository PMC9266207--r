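Package: nav16sim
Title: Markov-Model Simulation and Whole-Cell Analysis of Nav1.6 Channel
    Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Kinetic modelling toolkit for the voltage-gated sodium channel
    Nav1.6 (SCN8A) and its modulation by CaMKII. Implements a 13-state Markov
    gating scheme with six built-in parameter conditions (wild type, the
    epilepsy-associated variants R639C and R850Q, each with and without
    CaMKII inhibition), simulated whole-cell voltage-clamp protocols
    (current-voltage families, steady-state inactivation, recovery from fast
    inactivation), the standard electrophysiological analysis chain
    (conductance transform, Boltzmann activation/availability fits,
    biexponential decay and single-exponential recovery fits, current-density
    normalisation), a synthetic whole-cell recording generator with known
    ground truth, and single-compartment pacemaking-neuron simulations with
    heterozygous mutant channel expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
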