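Package: neuronsr
Title: Stochastic Hodgkin-Huxley Neurons and Stochastic Resonance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation of single-neuron membrane patches with finite
    Markov-chain ensembles of sodium and potassium channels (channel-state
    tracking), driven by a constant presynaptic current, a weak sinusoidal
    voltage signal, and Lorentzian-filtered Gaussian voltage noise. Includes
    the full analysis chain for signal encoding: spike detection,
    uniform-height pulse trains, run-averaged periodograms, and
    signal-to-noise ratio estimates with correlated-error propagation, plus
    sweep drivers over signal frequency and exogenous noise power to locate
    the stochastic-resonance optimum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
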