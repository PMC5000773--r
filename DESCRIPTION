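Package: placentaflux
Title: Compartmental Modelling of Tracer Phenylalanine Transfer in the
    Perfused Human Placenta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates carrier-mediated transfer of tracer phenylalanine
    across the ex vivo perfused human placental cotyledon with a
    three-compartment ordinary differential equation model: a
    trans-stimulated amino acid exchanger at the microvillous membrane,
    an exchanger and a facilitated transporter at the basal membrane,
    perfusate flow, first-order metabolic incorporation into protein,
    and paracellular diffusion.  Implements the stepwise maternal/fetal
    flow protocol used in dual placental perfusion experiments,
    steady-state analysis, deterministic calibration of maximal
    transport rates and the metabolic constant against uptake/transfer
    targets, five-fold parameter sensitivity analysis, two-way flow
    ANOVA and model-versus-data regression, radiotracer mass-balance
    accounting (quench correction, free/protein partition, tissue
    concentration and basal-membrane gradient estimation), and a
    synthetic perfusion dataset generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
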