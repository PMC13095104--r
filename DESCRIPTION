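Package: ffisim
Title: Feedforward Inhibition Sharing in a Spiking Model of the Striatum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Conductance-based leaky integrate-and-fire simulation of a
    cortico-striatal microcircuit in which medium spiny neurons (MSNs)
    receive direct cortical excitation and relayed feedforward inhibition
    from a small population of fast-spiking interneurons (FSIs). The
    package builds fixed-indegree random networks with lognormal synaptic
    weights, generates correlated Poisson cortical drive from overlapping
    source pools with controlled within- and between-group input sharing,
    integrates the network with an exponential-Euler clock-driven engine,
    and computes the spike-train statistics used to characterise the
    circuit: across-trial population Fano factors, pairwise spike-count
    correlation transfer, burst indices, and the response of a downstream
    pallidal readout neuron.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
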