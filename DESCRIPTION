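Package: agecircuit
Title: Aging Cortical Microcircuit Simulation and EEG Biomarker Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the effects of cellular and synaptic aging mechanisms
    (inhibitory interneuron loss, NMDA conductance loss, dendritic spine loss)
    on a surrogate human layer 2/3 cortical microcircuit, and extracts EEG
    biomarkers of those mechanisms. Provides data-driven derivation of aging
    parameters from published per-year loss rates and spine geometry, a
    four-population conductance-based spiking network with Ornstein-Uhlenbeck
    background drive and stimulus protocols, an analytic four-sphere
    volume-conductor EEG forward model, aperiodic/periodic power-spectrum
    parameterization and wavelet oscillation-event detection, signal-detection
    and spike-count decoding metrics, and a multilayer-perceptron classifier
    with Shapley-value feature attribution that identifies which aging
    mechanism produced a given EEG feature vector.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
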