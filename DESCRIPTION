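Package: elsm
Title: Extended Liquid State Machines for Spike-Based Pattern Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and simulates extended liquid state machines (ELSM):
    sparse recurrent reservoirs of conductance-based leaky integrate-and-fire
    neurons on a 3D grid with distance-dependent connectivity, per-synapse
    transmission delays, excitatory/inhibitory balance tuning of the
    input-inhibitory weight distribution, spike-frequency adaptation via an
    adaptive firing threshold, and heterogeneous membrane time constants.
    Includes the audio-style preprocessing pipeline (step-forward spike
    encoding of cochleogram-like matrices, bipolar-to-unipolar channel
    doubling, alignment and binning of event streams), a spike-count
    logistic-regression readout, low-bit synaptic weight quantization, a
    synthetic fixture generator for download-free experiments, and a
    command-line driver for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
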