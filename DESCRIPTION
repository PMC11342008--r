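Package: ziptraj
Title: Zero-Inflated Poisson Trajectory Groups and Linguistic Markers for
    Online Suicide-Risk Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Group-based trajectory modelling of per-period posting volume
    with a zero-inflated Poisson mixture likelihood, a model-selection
    ladder (BIC, AIC, normalized entropy, group composition, average
    posterior probability), dictionary-based psycholinguistic feature
    extraction with normalized word frequencies, per-period Poisson
    rate-ratio group contrasts, and a marker-selection cascade ending in
    multivariate logistic odds ratios. Ships a synthetic-cohort generator
    emulating a two-group cohort of 6163 forum users observed over seven
    half-year windows spanning the COVID-19 pandemic, so the full pipeline
    is reproducible without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
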