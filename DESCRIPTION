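Package: ebtsim
Title: Cell Survival Modelling and Injury Simulation for
    Electroporation-Based Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits the Peleg-Fermi family of cell-survival models
    (single-exponential, modified double-exponential, and power-law
    variants) to electroporation viability data via the two-step
    procedure, builds a cell-specific coefficient database for twenty
    human digestive-system cell lines, generates synthetic viability
    datasets with the statistical structure the fits assume, and runs a
    two-dimensional coupled electric-field / Pennes-bioheat / Arrhenius
    simulation with two needle electrodes to map electrical-injury and
    thermal-injury probabilities and their relative area ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
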