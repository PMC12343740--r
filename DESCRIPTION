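Package: flywasp
Title: Single-Generation Host-Parasitoid Emergence Modelling and
    Additivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing factorial heat-timing experiments on
    Drosophila hosts and their larval parasitoid wasps. Implements a
    single-generation variant of the Nicholson-Bailey host-parasitoid
    model for expected fly and wasp emergence from vials of eggs, fits
    stage-specific mortality, attack-rate and conversion parameters from
    control treatment arms by closed-form moment inversion with bootstrap
    uncertainty, projects null (additive) emergence distributions by
    stochastic simulation, and flags higher-order heat-by-parasitism
    effects when observed and simulated 95 percent confidence intervals
    do not overlap. Includes host-survival and parasitism-rate response
    metrics and a synthetic vial-count generator for fully crossed
    designs with optional injected synergy or antagonism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
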