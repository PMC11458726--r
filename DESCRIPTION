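Package: advwish
Title: Adventitious Error and Augmented Uncertainty for Relations
    Between Variables and Composite Scores
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models adventitious error: the random distortion of a
    theoretical population covariance matrix into a study-specific
    operational covariance matrix, formalized as an inverse-Wishart draw
    whose dispersion equals the squared RMSEA. Provides the generative
    simulator (theoretical -> operational -> sample covariance),
    closed-form augmented standard errors and the theoretical augmented
    uncertainty factor, between-study heterogeneity (tau) on the Cohen's
    d scale, Fisher-z power and sample-size calculations under effect
    heterogeneity, maximum-likelihood fitting of small one-factor and
    MIMIC covariance structure models with Thurstone regression factor
    scores, and two Monte Carlo studies: simulation-based augmented
    uncertainty factors for regression and factor-model effects, and the
    within-individual variability of standardized factor and summed
    scores induced by adventitious error alone.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
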