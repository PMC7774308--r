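Package: txspkpd
Title: Population PK/PD Modelling of an Irreversible Thromboxane-Synthase
    Inhibitor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Semi-mechanistic population pharmacokinetic/pharmacodynamic
    analysis of an oral anti-platelet agent in beagle dogs: a one-compartment
    model with first-order absorption and saturable Michaelis-Menten
    elimination coupled to a turnover model with irreversible inactivation of
    thromboxane synthase, mapping active enzyme to the platelet aggregation
    rate. Includes trial simulation with log-normal inter-individual
    variability and proportional or mixed residual error, sequential
    population PK then PD estimation by extended least squares (two-stage and
    naive-pooled), structural model comparison, goodness-of-fit and
    conditional weighted residual diagnostics, visual predictive checks,
    multiple-dose prediction, and non-compartmental analysis with a
    dose-proportionality test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
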