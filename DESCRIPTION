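Package: irtnorms
Title: Item Response Theory Psychometrics and Regression-Based Norms for
    Pediatric Neuropsychological Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calibration and scoring of dichotomous (two-parameter logistic)
    and ordered polytomous (graded response) item response theory models via
    marginal maximum likelihood EM, with test information, standard error of
    measurement and reliability curves; ordinal evidence for
    unidimensionality (polychoric correlations, diagonally-weighted
    one-factor analysis, ordinal alpha); sex differential item functioning
    screening by ability-anchored logistic regression with iterative
    purification; demographic norm regressions with exhaustive subset
    selection, repeated k-fold cross-validation and standard diagnostics;
    and conversion of ability estimates into demographically adjusted
    percentile ranks. Ships published item parameter banks and norm
    equations for the Rey-Osterrieth Complex Figure (copy and immediate
    recall) and the Shortened Version of the Token Test in a pediatric
    cohort, plus a synthetic-cohort generator reproducing the study's
    demographic and latent-trait structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    mvtnorm,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
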