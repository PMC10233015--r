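Package: retisim
Title: Biophysical Simulation of the Cone Pathway in Health and Retinal
    Degeneration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conductance-based network simulation of a parafoveal patch of
    the cone pathway of the retina (photoreceptors, horizontal, bipolar,
    amacrine and ganglion cells on hexagonal mosaics), with graded sigmoid
    synapses, seven-channel Hodgkin-Huxley ganglion cells, light and
    extracellular disk-electrode stimulation, staged retinal-degeneration
    transforms (outer-segment truncation, cell death, cell migration), and
    an analysis suite covering spontaneous rates, first-spike latencies,
    electrical activation thresholds, frequency-current curves and
    regularized generalized-linear-model receptive-field estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Matrix,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml,
    optparse
Config/testthat/edition: 3
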