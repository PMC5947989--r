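Package: loomsel
Title: Spatial-Coherence Selectivity of Looming-Sensitive Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how a collision-detecting neuron discriminates the
    spatial coherence of looming stimuli through interactions between
    hyperpolarization-activated (HCN) and inactivating potassium conductances.
    Provides generation of standard, coarse and coherence-degraded looming
    stimuli with an optimal-assignment spatial-coherence metric; Hodgkin-Huxley
    style voltage- and calcium-gated channel models with fitted HCN kinetics; a
    branched compartmental cable solver (Crank-Nicolson with Hines ordering)
    including current/voltage clamp, space-clamp analysis and Rall
    equivalent-cylinder reduction; retinotopic mapping of visual stimuli onto
    excitatory dendritic synapses; an intracellular-electrophysiology analysis
    suite (sag, membrane time constant, HCN activation fits, simulated EPSP
    summation, firing-rate and coherence-preference statistics, BCa bootstrap);
    synthetic-data generators for closed-loop validation; and scripted
    in-silico experiments reproducing channel-blockade and input-randomization
    protocols.
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
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
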