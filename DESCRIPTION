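Package: anoxbal
Title: Carbon and Reductant Balance Accounting for Anoxic Soil Incubations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for intermediary-ecosystem-metabolism accounting in anoxic
    peat microcosms. Computes per-compound carbon and electron-equivalent
    (degree-of-reduction) conversion factors from molecular formulas, net
    carbon and reductant turnover over incubation time frames with matched
    control subtraction, recovery (mass-balance closure) statistics,
    closed-chamber greenhouse-gas fluxes with CO2:CH4 ratio series, and the
    unit conversions used for slurry incubations. Includes an element- and
    electron-balanced kinetic simulator of the anaerobic food chain (primary
    fermentation, syntrophic oxidation, methanogenesis, acetogenesis, with
    bromoethanesulfonate inhibition) that provides ground truth for every
    accounting stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    withr,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
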