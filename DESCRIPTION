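Package: imbalnet
Title: Imbalanced Amplification in Balanced Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and mean-field analysis of recurrent
    excitatory/inhibitory networks of adaptive exponential
    integrate-and-fire neurons driven by strong feedforward input.
    Implements the balanced-rate solution, its linear finite-size
    correction, the nullspace decomposition that quantifies imbalanced
    amplification under partial (optogenetic-style) stimulation, and a
    Fourier-domain solver for continuously indexed networks with
    wrapped-Gaussian distance- and orientation-dependent connectivity,
    including surround-suppression, size-tuning and deconvolution
    analyses. A compiled forward-Euler core integrates the full spiking
    network with current-based exponential synapses and Poisson drive so
    every theoretical prediction can be cross-checked against simulation
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
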