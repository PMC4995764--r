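Package: skillforage
Title: Event-Based Simulation of Skill Learning and Social Learning in
    Group Foragers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit, event-driven individual-based model of
    foragers that learn what to eat (Rescorla-Wagner reinforcement of
    expected rewards) and how to eat it (sigmoidal skill acquisition with
    practice), embedded in an evolutionary framework with energy-weighted
    selection and mutation of learning traits. Social influences on
    learning include local enhancement (an emergent by-product of group
    cohesion), stimulus enhancement (priming towards recently observed
    resource types) and observational learning (direct transfer of
    processing experience). The package provides the resource-landscape
    generator, the asynchronous event scheduler, diet and repertoire
    metrics, and harnesses for evolutionary, parameter-sweep and switch
    experiments, all returning tidy tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
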