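Package: hgtgame
Title: Coexistence of Competing Microbial Populations via Horizontal Gene
    Transfer in Oscillating Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-population Lotka-Volterra competition model with
    horizontal gene transfer (HGT) in fixed and fast-oscillating environments.
    Implements the exact time-dependent replicator dynamics with varying total
    abundance, the coarse-grained (period-averaged) dynamics with the emergent
    game payoffs xi and kappa induced by correlated oscillations of reproduction
    and gene-transfer rates, closed-form equilibria with stability analysis,
    classification of the (xi, kappa) phase plane into coexistence, exclusion,
    bistability and unbounded-growth regions with symbiosis sub-types and
    synergy detection, and an exact (Gillespie) stochastic counterpart of the
    elementary birth, competition-death and gene-conversion processes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
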