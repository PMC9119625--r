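Package: actogel
Title: Kinetic Flory-Stockmayer Theory of Actomyosin Network Gelation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mass-action chemical kinetics of actin polymerization and
    actin-binding-protein association (alpha-actinin linkers, NMIIA motor
    minifilaments, Arp2/3 branchers), coupled to a generalized
    Flory-Stockmayer (multi-type branching process) calculation of the
    fraction of actin monomers in finite clusters. Detects connectivity
    percolation (sol-gel transitions), classifies sol / motor-gel /
    linker-gel regimes, performs Maxwell constraint counting for rigidity
    percolation with per-bond flexibility, solves the two-step
    non-cooperative linker binding equilibrium, and validates the analytic
    theory against a seedable Monte-Carlo branching-process oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
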