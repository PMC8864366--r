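Package: kinevo
Title: Multi-Level Evolutionary Simulation of Kinship Structures and Descent Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of competing societies of families whose
    cultural traits and mate preferences coevolve under cooperation and
    mating-competition pressures, together with the machinery to detect
    emergent clans in trait-preference space (k-sweep clustering with a
    Bayesian information criterion), trace marriage and descent relationships
    between clans, and classify kinship structures (clan endogamy, dual
    organization, generalized and restricted exchange) and descent systems
    (patrilineal, matrilineal, double). Includes phase-diagram sweep
    experiments over the cooperation and competition mortality parameters, the
    analytic phase-boundary condition between clan endogamy and dual
    organization, and an empirical estimation pipeline for cross-cultural
    ethnographic tables in the style of the Standard Cross-Cultural Sample.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
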