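Package: stripalloc
Title: Probability Models for the Italian Surplus-Organ Continuous-Strip Allocation Protocol
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An executable probability engine for the Italian national protocol for the
    management of surplus (excess) donor lungs. Implements the rotating "continuous strip"
    offer cascade between two macroareas, an exact Markov chain over joint strip states
    giving each transplant centre's probability of obtaining the t-th surplus organ, a
    correlated-binomial (Bahadur) and Poisson-binomial model of the probability of obtaining
    at least k of M organs, and a vectorised Monte Carlo season simulator used both for
    large configurations and as a validation oracle. Nations are described by a declarative
    YAML/JSON configuration (macroareas, strips, regions, acceptance rates, surplus
    production); a fixture reproduces the Italian two-macroarea lung setting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
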