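Package: rampkit
Title: Pharmacology and Conformational-Transition Analysis for CLR-RAMP Receptor Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for alanine-scan pharmacology and activation-transition
    modelling of the calcitonin receptor-like receptor (CLR) in complex with receptor
    activity-modifying proteins (RAMPs). Implements three-parameter logistic fitting of
    cAMP concentration-response data, the expression-corrected difference in log relative
    activity (delta log(Emax/EC50)) with full error propagation, ELISA cell-surface
    expression and competition-binding normalisation, positional-fluctuation principal
    component analysis of Calpha ensembles, fixed-increment essential-dynamics driving of
    an inactive-to-active transition on a toy elastic-network engine, and trajectory
    metrics (interhelical distances, persistent contacts, contact-rearrangement tables,
    helix bend angles, representative frames). Includes synthetic-data generators for
    both the pharmacology and the seven-helix bundle geometry so every analysis is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
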