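Package: nicokin
Title: Pyrolysis and Formation Kinetics of Nicotine in Mainstream Cigarette
    Smoke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for pseudo-first-order kinetic analysis of nicotine in
    mainstream cigarette smoke. Extracts temperature-resolved destruction
    rate constants from pyrolysis yield curves, fits Arrhenius and modified
    (Kooij-type) Arrhenius parameters, solves the consecutive two-step
    reaction model (nicotine -> pyridinyl radical -> pyridine) analytically
    and numerically to infer the unobservable radical intermediate, and
    estimates formation kinetics from puff-time series. Includes a seeded
    synthetic-data generator with known ground truth for parameter-recovery
    studies, CSV readers/writers and a JSON/markdown reporting layer with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
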