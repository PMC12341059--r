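Package: bksingle
Title: Single-Channel BK Current Analysis and Stochastic Gating Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-channel large-conductance
    calcium- and voltage-activated potassium (BK) channel recordings:
    continuous-time Markov gating simulation of cell-attached patch sweeps,
    all-points-histogram level detection, half-amplitude threshold
    idealization, NPo/Po and channels-per-patch estimation, unitary
    current-voltage slope conductance, log-binned dwell-time histogram
    fitting of open and closed time constants, allele-specific read pileup
    counting with exact imbalance tests, and the group-comparison ladder
    (Shapiro-Wilk routing to ANOVA/Bonferroni or Kruskal-Wallis/Dunn, with
    per-voltage Mann-Whitney comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    minpack.lm,
    generics,
    stats,
    utils
Suggests:
    Rsamtools,
    GenomicRanges,
    IRanges,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
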