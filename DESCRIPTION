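Package: snnkit
Title: Modular Behavior-Based Spiking Neural Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discrete-time spiking neural network simulation built from small
    behavior modules attached to neuron groups, synapse groups and the network
    under globally ordered integer priority keys. Provides vectorized
    synaptic-transmission and spike-timing-dependent plasticity (STDP) kernels
    together with their naive reference implementations, masked weight
    clipping, interval weight normalization, reduced-precision weight storage,
    a sparse-weight fallback, two reference network models (leaky
    integrate-and-fire neurons with one-step STDP, and Izhikevich neurons with
    trace STDP), and a benchmark harness that validates the optimized kernels
    against the naive oracles and measures their relative performance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
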