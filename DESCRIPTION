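Package: mprfit
Title: Membrane Potential Resonance in Conductance-Based Neuron Model Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study membrane potential resonance (MPR) in voltage clamp
    with a single-compartment conductance-based model of the crab pyloric
    dilator (PD) neuron carrying a leak current, a hyperpolarization-activated
    inward current (IH) and an inactivating low-threshold calcium current
    (ICa). The package generates logarithmic ZAP voltage-clamp commands,
    integrates the clamped gating dynamics, measures cycle-by-cycle impedance
    amplitude and phase profiles, reduces them to the ten scalar attributes
    that characterize resonance, and fits populations of model parameter sets
    to a target attribute set with the NSGA-II multi-objective evolutionary
    algorithm. Downstream analyses cover pairwise parameter correlations with
    permutation tests, partitioning of the fitted population by calcium
    conductance, re-profiling under a lowered voltage floor, and 1D/2D
    sensitivity analysis of resonance attributes along parameter correlation
    lines.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
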