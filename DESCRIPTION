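Package: rstarevo
Title: Evolution of Competitive Ability for Essential Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how microbial competitive abilities for
    essential resources evolve. Fits Monod and salt-tolerance growth models
    to population-level fluorescence time series, derives minimum resource
    requirements (R*) with residual-bootstrap confidence intervals,
    quantifies ancestor-to-descendant trait change and trade-off structure,
    and predicts pairwise competitive outcomes (stable or unstable
    coexistence, competitive exclusion) under resource competition theory,
    validated against a mechanistic chemostat model. Includes a synthetic
    data generator emulating a chemostat selection experiment so that the
    whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    withr,
    ggplot2,
    generics,
    minpack.lm,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
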