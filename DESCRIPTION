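Package: riskgame
Title: Threshold Public-Goods Games with Central and Peer Punishment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based Monte Carlo simulation of a collective-risk
    (threshold public-goods) game in which subgroups must jointly reach a
    contribution threshold or every member loses all resources.  Supports
    pool-funded central punishment of defectors, decentralized many-to-many
    peer punishment, Fermi pairwise imitation dynamics and mutation.
    Provides tidy sweep orchestration over punishment intensities and risk
    thresholds, and the summary statistics used to study sanctioning
    regimes: collaboration rate, punishment enhancement of collaboration,
    cost-benefit ratios of each punishment type, and resource wastage with
    zone labels.  The simulation core is compiled (Rcpp) with a pure-R
    reference engine that reproduces it draw-for-draw.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
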