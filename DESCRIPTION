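Package: eipcea
Title: Cost-Effectiveness Modelling of Early Intervention in Psychosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic economic evaluation of Early Intervention in
    Psychosis (EIP) services against community mental health teams: a
    six-state Markov cohort model with 3-month cycles driven by a Bayesian
    power-prior evidence synthesis (random-effects binomial meta-analysis
    pooling aggregate trials with a downweighted observational cohort),
    incremental cost-utility analysis (ICER, net monetary benefit,
    acceptability curves), probabilistic and deterministic sensitivity
    analysis, and value-of-information analysis (EVPI, population EVPI and
    regression-based partial EVPI). Includes synthetic-data generators with
    known ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    rjags,
    coda,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
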