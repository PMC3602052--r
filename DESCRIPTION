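Package: survbench
Title: Benchmarking Health-Care Systems with Stage-Specific Relative Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-sectional and longitudinal benchmarking of health-care
    "objects" (countries, states, districts, registries) against a fixed
    reference object, combining disease-stage case distributions with
    stage-specific relative survival rates. Implements the extended
    standardized screening index (eSSI), the standardized case-mix (SCI),
    work-up (SWI) and treatment (STI) indices, and the composite measures
    OPE (SCI x SWI x STI) and ROPI ((1/eSSI) x SWI x STI), all defined as
    observed-over-expected ratios against the reference. Includes a reader
    and validator for long-format registry summary tables, a deterministic
    synthetic-registry generator for testing, trend plots, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
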