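Package: radyield
Title: Charged-Particle Activation Yield Modelling for Radionuclide Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models accelerator-based radionuclide production on thin enriched
    targets: Bethe-Bloch electronic stopping power and CSDA ranges for light
    ions, thin-target range-averaged reaction cross sections, beam flux and
    production/burn-up rates, closed-form Bateman production-decay chain
    inventories with a constant source term, and derived yield, activity,
    radionuclidic purity and specific-activity reports. Ships a calibrated
    excitation-function library and a configuration-driven scenario runner
    for lutetium-177 production from deuterons on ytterbium-176 oxide,
    including a target-thickness/beam-energy figure-of-merit optimizer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
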