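Package: thnsim
Title: Agent-Based Simulation of Take-Home Naloxone Distribution with Jail Circulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A daily-tick stochastic agent-based simulator of opioid-related
    overdose events and deaths in a synthetic urban population with jail
    circulation. Person-level overdose hazards follow a multiplicative
    relative-risk model (sex, injection route, age, and post-release windows);
    survival of a witnessed overdose is resolved through a bystander
    intervention probability tree. Take-home naloxone (THN) kits are
    distributed through community, jail-release, and peer-network channels,
    and the package evaluates intervention scenario grids with common random
    numbers, global sensitivity screening via Sobol/Saltelli designs, and
    cost-per-death-averted / number-needed-to-treat outcome metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lhs,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
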