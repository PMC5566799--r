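Package: striatnet
Title: Spiking Dynamics of Inhibitory Networks with Distance-Dependent Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of purely inhibitory spiking networks with
    distance-dependent connectivity on a two-dimensional torus, modelled on the
    striatal network of medium spiny neurons. Provides a conductance-based
    leaky integrate-and-fire simulator with alpha-function synapses and
    calibrated unitary PSP amplitudes, polar-sampling wiring for gamma
    (off-centre) and Gaussian (on-centre) connection kernels, a neural-field
    linear stability analysis that predicts when spatially periodic activity
    bumps emerge and at what spacing, Mexican-hat (Ricker) bump detection and
    tracking on 100 ms activity frames, and spike-train and stimulus-response
    statistics (rates, CV of interspike intervals, Fano factor, pairwise
    correlation spectra) used to classify asynchronous-irregular, transition
    and winner-take-all network states.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
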