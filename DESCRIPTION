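Package: gbas
Title: Modelling and Signal Decoding for Glucometer-Based Allosteric Biosensors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for glucometer-based allosteric
    sensors (GBAS), in which a ligand-binding domain inserted into
    PQQ-dependent glucose dehydrogenase couples drug binding to the rate of
    glucose oxidation. Provides allosteric Michaelis-Menten kinetics and a
    colorimetric (DCPIP) assay forward model, amperometric staircase trace
    simulation with steady-state extraction and background correction, a
    ratiometric dual-electrode decoder with first-order error propagation
    that emits a binary ligand call, a Nernstian enzymatic fuel cell and
    organic electrochemical transistor (OECT) readout model, two-round
    domain-insertion library screening statistics including coupon-collector
    coverage probability, and seeded synthetic-data generators so every
    stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
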