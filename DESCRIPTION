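Package: tspoquant
Title: Kinetic Quantification of TSPO PET in Longitudinal Rodent Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantification of dynamic [11C]-(R)-PK11195 PET
    time-activity curves in longitudinal small-animal studies of
    neuroinflammation. Builds metabolite-corrected arterial plasma input
    functions from sparse blood-sample tables (biexponential parent-fraction
    model with an early plateau, straight-line plasma-over-blood ratio),
    derives input functions for sessions without blood sampling by
    dose-and-weight rescaling, and constructs a cohort mean input function.
    Quantifies regional curves with the Logan plot, one- and two-tissue
    compartment models, the Logan reference method, the simplified reference
    tissue model (basis functions) and standardized uptake values, and
    aggregates results with the bilateral-significance convention, percent
    changes, coefficients of variation and paired tests. A seeded synthetic
    cohort generator emulating a three-session rat epileptogenesis design
    makes every pipeline stage testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
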