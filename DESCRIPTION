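Package: reacloop
Title: Reactive Bioreactor Experiment Simulation, Cytometry Processing and
    Model-Predictive Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free, fully testable implementation of the computational
    core of a reactive bioreactor-automation platform: flow-cytometry event
    processing (gating, spectral deconvolution, forward-scatter normalization to
    relative promoter units, genotype classification), a two-variable ODE model
    of EL222 light-inducible gene expression with receding-horizon
    model-predictive control of duty-cycled light, steering of a two-strain
    consortium ratio via optical-density setpoints, competition-assay fitness
    inference from log-odds slopes, simulated instruments (multi-strain
    turbidostat with histidine-limited Monod growth, plate reader with
    evaporation-compensated dilution protocols), and an event-driven experiment
    orchestrator with exhaustive JSON-lines logging and deterministic replay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
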