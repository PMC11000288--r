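Package: protodoe
Title: Box-Behnken Design and RSM/ANN Optimization of Protoplast Preparation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing plant protoplast preparation conditions (and
    similar three-factor laboratory protocols) from small designed experiments.
    Generates Box-Behnken designs, fits full second-order response-surface
    models with the complete ANOVA adequacy panel (lack of fit, pure error,
    PRESS-based predicted R-squared, coefficient of variation, adequate
    precision), trains single-hidden-layer back-propagation networks with
    Levenberg-Marquardt or scaled-conjugate-gradient updates, searches factor
    boxes with a real-coded genetic algorithm or Derringer desirability, and
    compares model families by R, R-squared, RMSE and MAPE. Ships the 17-run
    Salsola laricifolia protoplast study data and a synthetic response-surface
    generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
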