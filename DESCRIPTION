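Package: petkin
Title: Dual-Tracer PET Kinetic Modelling of Cardiorenal Time-Activity Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and compartmental kinetic analysis of dynamic
    carbon-11 PET time-activity curves (TACs) for the heart and kidney,
    built around a dual-tracer acetoacetate/acetate protocol. Provides a
    Feng-type arterial input function simulator with frame-schedule
    averaging and activity-dependent noise, one-tissue and irreversible
    two-tissue compartment forward models computed by exact
    piecewise-linear convolution, carbon-11 decay and plasma metabolite
    corrections, weighted nonlinear least-squares parameter estimation
    with AIC model comparison, derived physiological metrics (SUV,
    rate-pressure-product-scaled uptake, myocardial blood flow via a
    Renkin-Crone extraction model, oxygen consumption from clearance),
    renal-pelvis double-peak detection, and cohort-level paired
    statistics with a publication-style summary table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
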