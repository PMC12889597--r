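Package: erade
Title: Energy Rank Alignment for Simulated Directed Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates machine-learning-guided directed evolution campaigns in
    which a generative sequence policy over a set of mutated residue positions
    is iteratively aligned to experimental fitness with energy rank alignment
    (ERA), a preference-optimization objective whose target is an
    entropy-regularized Gibbs-Boltzmann distribution over variants. Provides
    combinatorial multi-site fitness landscapes (file I/O, fitness scaling, a
    tunably epistatic synthetic generator), tabular factorized and joint
    sequence policies with pseudo-likelihoods and constrained sampling, the
    ERA and DPO pairwise losses with a gradient trainer and the closed-form
    optimal-policy oracle, the iterative sample-assay-align campaign loop with
    replicate management and benchmark metrics, and diagnostics for landscape
    ruggedness (local optima ratio, roughness-slope ratio, neutrality, global
    optimum accessibility, epistasis classification) and for policy
    distributions (entropy, mode-seeking statistics, fitness correlation,
    probability-mass fold change, likelihood-weighted position frequency
    matrices).
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
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
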