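Package: gatesim
Title: Cav3.3 T-Type Channel Gating, Voltage-Clamp Simulation and
    Thalamic Neuron Firing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hodgkin-Huxley style model of Cav3.3 (T-type) calcium channel
    gating with parameter sets for the wild-type channel and the
    gain-of-function variants I860N, I860M, I1306T and M1425I. Simulates
    whole-cell voltage-clamp recordings (current-voltage families,
    steady-state inactivation, tail-current deactivation and action
    potential clamp trains), provides the standard current-analysis
    pipeline (peak/IV analysis, Boltzmann fits of fractional activation
    and inactivation, mono-exponential kinetic fits, window-current
    comparison, charge metrics), and embeds the channel in a
    single-compartment conductance-based thalamic reticular nucleus
    neuron to convert gating parameters into firing phenotypes
    (rheobase, burst duration, initial and steady-state frequencies,
    firing-mode classification).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
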