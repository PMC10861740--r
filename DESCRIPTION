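Package: icubench
Title: Severity-Adjusted Benchmarking of ICU Resource Use and Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cost-based standardized resource use ratios (costSRUR) and
    standardized mortality ratios (SMR) for multi-unit intensive care
    registries. Implements SAPS II stratification, expected resource use
    per hospital survivor, cost allocation by length-of-stay or TISS-76
    share with currency and purchasing-power-parity adjustment,
    organ-donor sensitivity variants, and bivariable gamma regression of
    unit-level structural factors against the benchmarking ratios.
    Includes a synthetic multi-unit registry generator with injectable
    unit-level distortions for parameter-recovery validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
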