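Package: dfft
Title: Density-Functional Fluctuation Theory for Crowd Density Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing binned counts of crowding agents (walking
    insects, milling animals, people) with density-functional fluctuation
    theory. A crowd is modelled by a per-bin "vexation" encoding location
    preference and an occupancy-dependent "frustration" encoding social
    interactions; bin counts then follow a modified Poisson law whose
    deviations from the Poisson form identify the interactions. The package
    simulates crowds with a Barker-rule Markov chain, extracts vexation and
    frustration from count fluctuations by maximum a posteriori inference
    with Fisher-information uncertainties, and predicts density
    distributions for new populations and arenas by recombining extracted
    functions under a grand-canonical chemical potential.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
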