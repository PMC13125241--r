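Package: aacircuit
Title: Approach-Avoidance Conflict Simulation and Intracranial Theta-Circuit Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a continuous-choice approach-avoidance conflict task
    (a corridor foraging game with a distance-dependent attack hazard),
    generates trial-structured multichannel local field potential surrogates
    with known ground-truth theta coupling, and implements the analysis
    chain used to characterize prefrontal-limbic theta circuits from
    intracranial recordings: Morlet time-frequency power with inter-trial
    interval z-scoring, across-trial theta coherence (imaginary coherence,
    pairwise phase consistency, debiased weighted phase-lag index) with
    trial-shuffle permutation nulls and duration rules, time-reversed net
    spectral Granger causality, concatenated-approach cross-correlation lag
    analysis, amplitude-envelope synchrony, and hierarchical Bayesian mixed
    models summarized by the posterior probability of direction (P+).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rjags,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
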