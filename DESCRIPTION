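Package: demburden
Title: Multi-State Cohort Projection of Dementia and Disability Burden
    Under Diabetes Prevalence Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting the future burden of dementia, disability
    and mortality in an ageing population under alternative diabetes
    prevalence scenarios.  Implements a ten-state open-cohort Markov model
    (eight alive states crossing cardiovascular disease with cognitive
    impairment, dementia and disability, plus two cause-specific death
    states), penalized-spline smoothing and log-linear extrapolation of
    cause-specific mortality trends, a duration-stratified multi-category
    population attributable risk fraction (PARF) mechanism that rescales
    affected transition probabilities, scenario-comparison outcome measures
    (incident cases, deaths avoided, life-years gained, percentage of life
    spent with disability), and Monte Carlo probabilistic sensitivity
    analysis with percentile uncertainty intervals.  A seeded synthetic-data
    generator supplies model inputs with the statistical structure the
    analysis assumes, so the full pipeline runs reproducibly without any
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
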