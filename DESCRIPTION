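Package: seasonmort
Title: Seasonal Fluctuations in Cohort Mortality and Their Contribution
    to Life Expectancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing seasonal (winter-excess) fluctuations in the
    mortality of extinct birth cohorts. Daily death counts are modelled by a
    Gompertz (exponential-age) hazard modulated by a one-year sinusoid and
    fitted by Poisson regression on the piecewise-exponential likelihood, or
    by direct maximisation of the person-level survival likelihood. The
    within-year peak-to-trough mortality rate ratio summarises the magnitude
    of seasonality, with parametric-bootstrap confidence intervals. The fitted
    hazard is decomposed into an age-driven lower-bound part and a seasonal
    multiplicative part, and cohort life expectancy at 60 is computed under
    the actual and the counterfactual (seasonality-free) hazard to attribute
    longevity gains to the quenching of seasonal mortality. A synthetic cohort
    generator reproduces the person-level data schema so the full pipeline is
    testable without register data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
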