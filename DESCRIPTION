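Package: ssbstroke
Title: Proportional Multi-State Life Table Model of a Sugar-Sweetened
    Beverage Tax and Stroke
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the population health impact of a price increase on
    sugar-sweetened beverages (SSBs) on the burden of stroke. A tax scenario
    is translated into beverage consumption changes via own- and cross-price
    elasticities, into net daily energy intake, into an equilibrium body
    weight change, and into a shift of the log-normal BMI distribution of
    each age-sex stratum. The potential impact fraction for stroke incidence
    is obtained by integrating a relative-risk curve over the reference and
    shifted BMI densities, and fed into a proportional multi-state life
    table that follows 5-year cohorts by single year of age until age 100,
    tracking incident and prevalent stroke cases, stroke and total deaths,
    (health-adjusted) life years and stroke health-care costs in a reference
    and an intervention arm. Includes a seeded synthetic-data generator that
    emulates the structure of the survey, burden-of-disease and claims
    inputs, Monte Carlo uncertainty intervals, and a deterministic
    sensitivity grid over tax rate, pass-on rate, portion size, discount
    rate, cost and disability scaling, BMI trend and elasticity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
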