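Package: critsync
Title: Critical Synchronization and 1/f Dynamics in Rich-Club Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of Izhikevich spiking dynamics on
    hierarchical scale-free networks with tunable rich-club connectivity and
    inhibitory/excitatory hub composition. Builds the deterministic
    Ravasz-Barabasi clique hierarchy, wires hub pairs with probability kappa,
    assigns neuron types (global hubs inhibitory or excitatory, local hubs
    inhibitory with probability eta), integrates the two-variable spiking model
    with second-order Runge-Kutta at 0.1 ms resolution, and quantifies the
    resulting collective dynamics: detrended fluctuation analysis of the global
    state, Hilbert-phase pairwise synchronization, the global lability of
    synchrony and its bounded-exponent power-law fit, firing-rate versus
    synaptic-weight calibration curves, and kappa-eta phase diagrams of the
    temporal scaling exponent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
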