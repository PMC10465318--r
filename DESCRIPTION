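Package: vitdmr
Title: Linear and Non-Linear Mendelian Randomization of Serum
    25-Hydroxyvitamin D and Adolescent Suicidality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An individual-level causal-inference pipeline for the relation
    between serum 25-hydroxyvitamin D (25(OH)D) and dichotomous suicidality
    outcomes (ideation, plans, attempts) observed over three annual waves.
    Provides an unweighted vitamin D polygenic score instrument with
    strength (F-statistic) and pleiotropy diagnostics; observational
    logistic models with fractional-polynomial non-linearity tests; linear
    Mendelian randomization by the ratio-of-coefficients method with
    first-order Taylor confidence intervals and a closed-form power
    calculation for binary outcomes; non-linear Mendelian randomization by
    decile-stratified localized average causal effects (LACE) with
    fractional-polynomial meta-regression, quadratic and Cochran's Q tests;
    sex-stratified variants; and a seeded synthetic-cohort generator that
    emulates the statistical structure the analysis assumes, so every stage
    can be exercised and calibrated without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
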