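Package: tempocon
Title: Temporal Contrastive Learning Through Non-Equilibrium Memory Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of Temporal Contrastive Learning (TCL), a
    local Hebbian-style learning rule in which each synapse convolves its
    synaptic current with a non-monotonic memory kernel and thresholds the
    result, so that a fast/slow sawtooth presentation of clamped and free
    states yields contrastive weight updates without explicit memory.
    Provides memory-kernel construction and characterization, single-synapse
    amplitude sweeps with dynamic-range and offset analyses, an energy-based
    layered network trained by TCL with an Equilibrium-Propagation reference,
    a reversible ladder Markov-chain model with Schnakenberg entropy
    production linking dissipation to learning accuracy, and ODE models of
    physical feedback units (integral feedback, negative autoregulation,
    Maxwell viscoelastic and RC elements) that realize the kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
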