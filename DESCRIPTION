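Package: boutmotion
Title: Bout-Structured Random Acceleration Model of Animal Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing individual animal movement
    driven by a Langevin equation with a bout-structured, exponentially
    correlated (non-Wiener) random forcing: the animal exerts a constant
    random force between successive environmental cues, cue arrivals follow
    a Poisson process, and the environment applies linear (Stokes) drag.
    Provides the closed-form mean squared displacement of the process
    together with its small-time, zero-drag, low-drag, high-drag and
    diffusive limits, transition-time analysis of the superballistic,
    superdiffusive and diffusive regimes (including the Lambert W
    approximation of the diffusive convergence time), and an exact-in-bout
    Monte Carlo simulator with ensemble estimators for the MSD, the
    dispersal kernel and the forcing autocovariance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
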