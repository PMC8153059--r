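Package: tumanet
Title: Tripartite-Synapse Network Simulation and Synchronous-Burst Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of Morris-Lecar neurons coupled by a
    four-state glutamate-recycling synapse model in which an astrocytic
    pool takes up synaptic glutamate and returns it slowly through the
    glutamate-glutamine cycle. Includes residual-calcium-driven
    asynchronous release, random excitatory/inhibitory network
    construction, a compiled fixed-step stochastic integrator, and the
    matching spike-train analysis layer: firing-rate time histograms,
    interspike-interval return maps, two-threshold synchronous-burst
    detection, burst statistics, and fluorescence trace utilities
    (delta-F/F detrending, transient decay-time estimation). Experiment
    drivers reproduce uptake- and recycling-timescale parameter sweeps
    and clamped-astrocyte control runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
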