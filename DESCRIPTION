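Package: reflexpool
Title: Motor Neuron Pool Simulation and Reflex Amplitude Estimation from
    Peristimulus Frequencygrams and Histograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a heterogeneous pool of two-compartment
    conductance-based spinal motor neurons driven by common and independent
    synaptic noise plus an excitatory postsynaptic current (EPSC) stimulus
    train, and estimates single-unit H-reflex amplitudes from the cumulative
    sums of the peristimulus frequencygram (PSF) and the peristimulus time
    histogram (PSTH). Includes discharge-statistics filters, an automated
    cusum-based reflex detector with an error-box significance test,
    surrogate spike-train generators with known injected responses for
    validation, and population-level analyses (standardized regression,
    one-tailed Pearson correlation, amplitude dispersion, empirical
    cumulative distribution comparisons across pool compositions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
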