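Package: mvebias
Title: Selection Bias in Measured Vaccine Effectiveness from Competing
    Heterogeneities
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation and analytic selection theory for how
    population heterogeneity in baseline susceptibility (frailty) and in
    vaccine-induced protection biases hazard-ratio based measured vaccine
    effectiveness (mVE) over time, even when individual protection is
    constant.  Provides gamma frailty and beta or antibody-derived
    protection distributions, a daily-hazard epidemic simulator with
    sterilizing immunity, Cox proportional-hazards estimation with
    time-category by vaccine interactions (TVI), cumulant-generating
    function formulas for the effect of selection on hazard rates and
    hazard ratios, power-law antibody waning linked to protection through
    a risk-correlate model and a within-host stochastic-extinction model,
    and scenario pipelines for offset statistics across heterogeneity
    grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    pracma,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
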