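Package: cachexim
Title: Feedback-Regulated Muscle Dynamics in Health, Cancer Cachexia, and
    ActRIIB-Blockade Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation models of skeletal-muscle tissue
    built on a two-compartment stem-cell lineage (satellite cells and
    myofibers) with negative feedback from muscle mass onto satellite-cell
    self-renewal and division. Extends the healthy model with exponential-
    linear tumor growth and tumor-induced perturbations that reproduce
    cancer-cachexia muscle wasting in the murine C26 model, and with
    efficacy multipliers describing soluble-ActRIIB anti-cachexia treatment.
    Provides closed-form steady states, numerical simulation, wound-healing
    and mechanism-sweep in-silico experiments, a three-stage calibration
    pipeline (logistic body-weight extension, simulated annealing, grid
    search on the root-mean-squared error), local one-at-a-time sensitivity
    analysis, and synthetic mouse-cohort generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
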