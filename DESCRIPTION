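Package: thalsync
Title: Thalamocortical Population Synchrony and Cortical Orientation Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decoding pipeline for the role of stimulus-driven
    thalamic population synchrony in cortical orientation selectivity. Builds
    synthetic LGN populations from receptive-field templates by spatial
    duplication under a receptive-field-separation distribution, converts
    receptive-field shifts into drifting-grating response latencies, quantifies
    population synchrony as timing jitter from the pooled spike-time
    autocorrelation, drives a leaky integrate-and-fire model of a layer 4
    cortical neuron through summed exponential EPSCs, and quantifies
    orientation information transmission through tuning curves, Poisson
    response models, Fisher information, the Cramer-Rao bound, and
    information per spike as a function of thalamic timing jitter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
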