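Package: pdtogrowth
Title: Treatment-Response Growth Kinetics for Patient-Derived Tumor
    Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ordinary-differential-equation models of patient-derived tumor
    organoid (PDTO) growth under chemotherapy, radiotherapy and combined
    chemoradiotherapy.  Growth follows logistic kinetics; treatment acts
    through time-varying Gaussian killing-rate pulses, with irradiated
    populations split into active and inactive compartments by the
    linear-quadratic survival model.  The package provides compiled ODE
    solvers, diameter/cell-number conversion for brightfield size
    measurements, bounded multi-start least-squares calibration of
    per-organoid trajectories with the group-specific fixed/free parameter
    schemes, population summaries with confidence intervals and across-line
    comparisons, a log-ratio treatment-response metric, killing-curve and
    forecast utilities, and a synthetic-study generator for validation by
    simulate-and-refit parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
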