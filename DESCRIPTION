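Package: antcoex
Title: Mechanistic Coexistence Modelling for a Temperate Ant Community Under Climate Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A temperature-dependent, hybrid dynamical model of coexistence in a
    three-species guild of ground-foraging ants (Prenolepis imparis,
    Aphaenogaster rudis, Nylanderia faisonensis) competing for discrete food
    patches. Within a year, patch occupancy is resolved daily by a
    quasi-steady-state linear solve driven by seasonal foraging and resource
    phenologies; between years, colony densities follow a discrete update that
    converts harvested food into new colonies. The package runs ensembles of
    randomly drawn resource microhabitats, trait-equalization experiments,
    phenological-shift and uniform-warming scenarios, single-species
    (no-competition) contrasts, and a Latin-hypercube / partial-rank-correlation
    sensitivity analysis of seasonal food supplementation, and summarises
    outcomes as community composition fractions, mean relative abundances and
    Pielou's evenness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    lhs,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
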