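Package: caninefm
Title: Food Motivation, Owner Management and Obesity Risk in Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying behavioural susceptibility to obesity in
    companion dogs. Scores owner-report questionnaire responses into food
    motivation and owner control composites, models breed
    underweight/ideal/overweight-obese probabilities from clinic body
    condition records using Firth bias-reduced logistic regressions merged
    into a three-category multinomial with simulation confidence intervals
    and covariate-standardized predictions, and relates breed-average food
    motivation to breed obesity probability. Includes a synthetic cohort
    generator with known ground truth for end-to-end validation, cohort
    filtering and recoding utilities, and linear modelling helpers
    (stepwise AIC minimal models, breed-adjusted food motivation, tertile
    stratified interaction effects).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
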