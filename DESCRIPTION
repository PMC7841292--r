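Package: hsnn
Title: Heterogeneous Spiking Neural Networks with STDP Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of feedforward spiking neural networks
    built from leaky integrate-and-fire neurons with heterogeneous membrane
    dynamics. Provides conductance-based STDP plasticity with soft bounds,
    rate encoding of image sequences, spiking convolutional layers with
    cross-depth and local winner-take-all inhibition, crossover memory
    pathways mixing short- and long-retention neurons, and a closed-form
    calculus for pathway response functions, cut-off frequencies and
    retention lengths, cross-validated against brute-force spiking
    simulation. Includes layer-wise unsupervised training, a multi-objective
    rate readout, and a synthetic generator of moving-object frame sequences
    with controlled translation and rotation dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
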