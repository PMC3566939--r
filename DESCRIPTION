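Package: cvdsim
Title: Monte Carlo State-Transition Microsimulation of Cardiovascular Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual-level Monte Carlo state-transition (microsimulation)
    modelling of coronary heart disease, stroke and mortality. Transition
    probabilities are derived from centered Cox proportional-hazards
    equations with annual cumulative baseline hazards; parameter uncertainty
    is represented by bootstrap-linked sets of transition functions; a
    three-level nested simulation separates parameter uncertainty,
    between-individual heterogeneity and first-order stochastic uncertainty.
    Includes recalibration of a fitted model to a new population by
    substituting centered baseline hazards and covariate means, an
    internal/predictive/external validation harness comparing observed with
    simulated cumulative incidences, and a synthetic-cohort generator with
    correlated risk factors and ground-truth event histories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
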