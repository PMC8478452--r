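Package: ferroflux
Title: Bioenergetics and Functional-Gene Profiling of Subsurface Iron Cycling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the viability of microbial iron metabolisms in
    deep-subsurface fracture fluids. Computes equilibrium constants and in situ
    Gibbs energies for a packaged library of 48 iron redox reactions from site
    geochemistry (unit conversion, ionic strength, extended Debye-Hueckel
    activity coefficients, Nernstian perchlorate estimation), scales exergonic
    reactions to limiting-reactant availability to obtain energy densities, and
    post-processes iron-gene annotation tables (dual-pipeline ambiguity
    reconciliation, relative-abundance normalization, pathway recategorization,
    Bray-Curtis/UPGMA site clustering, and genome-bin summaries). A synthetic
    data generator emulates annotation outputs with planted abundances so every
    stage is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
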