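Package: lifnet
Title: Multi-Layer Spiking Networks Trained by Global Random Feedback and
    Local Differential STDP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates discrete-time conductance-based leaky integrate-and-fire
    (LIF) networks and trains them without backpropagation. Layer-wise activity
    targets are delivered by fixed random feedback projections of the output
    error (the penultimate layer through the forward-weight transpose), and
    forward weights adapt by a local differential spike-timing-dependent
    plasticity rule. Includes IDX-format readers for MNIST-style image data, a
    synthetic Gaussian-blob dataset generator, evaluation by output argmax,
    depth sweeps, feedback-layer ablation, spike-raster export, and a command
    line interface for training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
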