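Package: mbinherit
Title: Stochastic Simulation of Microbial Inheritance in Host-Associated
    Microbiomes
Version: 0.1.0
Authors@R:
    person("mbinherit", "developers", role = c("aut", "cre"),
           email = "mbinherit@example.org")
Description: Neutral stochastic model of commensal microbiome assembly in a
    population of hosts with finite microbial carrying capacity. Within-host
    dynamics follow a Moran-type death-immigration-birth jump process; host
    turnover replaces dead hosts with newborns seeded by a beta-distributed
    split of a parent's microbiome (vertical transmission). Two interchangeable
    engines are provided: the exact discrete jump process and an
    Euler-Maruyama diffusion approximation. Includes population-level
    observables (occurrence, microbial load, inheritance-induced changes),
    lineage-taxon persistence analytics (extinction times, host-death
    thresholds), packaged scenario presets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
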