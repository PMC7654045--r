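# seasonmort

Seasonal (winter-excess) fluctuations in the mortality of extinct birth
cohorts, and what they cost in life expectancy.

In temperate climates, elderly mortality peaks every winter and troughs in
late summer. Over the 19th and 20th centuries the size of that swing
collapsed. `seasonmort` is for demographers and epidemiologists who have
person-level records (birth date, death date, sex) for complete — extinct —
birth cohorts and want to (i) measure each cohort's seasonal swing, and
(ii) attribute part of the growth in life expectancy to its disappearance.

## The model

For a cohort member born on day of year *b* (Jan 1 = 0), with follow-up
time *t* in days from January 1 of the year of the 60th birthday, the
per-day hazard is a Gompertz law modulated by a one-year sinusoid:

$$\lambda(t\mid b) = \mu\, e^{\beta (t+365-b)}\, e^{\alpha\cos(2\pi t/365.25 + \theta)}$$

Discretising to days makes daily death counts Poisson with mean
$N_t\lambda(t)$, so the model is fitted by Poisson regression with a
log-exposure offset (`fit_poisson()`); an exact person-level maximum
likelihood route (`fit_direct_ml()`) is provided as a cross-check and
agrees to ~0.1% on large cohorts. Three derived quantities do the
scientific work:

- **rate ratio** `h = exp(2*alpha - 182.625*beta)` — how many times
  deadlier winter is than summer, with parametric-bootstrap confidence
  intervals (`rate_ratio_ci()`);
- **decomposition** `lambda = M1 * M2`, where `M1 = mu*exp(-alpha) *
  exp(beta*(t+365-b))` is the *lower-bound mortality* (the rate under
  permanent late-summer conditions) and `M2 >= 1` carries all seasonality
  (`decompose_hazard()`);
- **counterfactual life expectancy at 60** — numerically integrating the
  lifetime density under `M1*M2` and under `M1` alone; the difference is
  the years of life lost to seasonality (`cohort_e60()`).

A synthetic-data module (`generate_study()`) draws person-level cohorts
from the same hazard, so the whole pipeline is testable without register
data.

## Worked example

Simulate one male cohort born 1820 (20,000 persons, amplitude 0.3,
February peak), fit it, and summarise:

```r
library(seasonmort)

sc <- scenario_config(1820, "male", 20000,
                      mu = 6e-5, beta = 2.4e-4, alpha = 0.3,
                      theta = -2 * pi * 41 / 365.25, seed = 7)
cohort <- generate_study(sc) |> build_cohort(1820, "male")
fit <- fit_poisson(build_daily_counts(cohort))
fit
#> <hazard_fit:poisson> [male 1820]
#> # A tibble: 4 × 3
#>   term       estimate  std.error
#>   <chr>         <dbl>      <dbl>
#> 1 intercept -9.67     0.0148
#> 2 beta       0.000238 0.00000240
#> 3 a1         0.190    0.0101
#> 4 a2         0.222    0.0101
#> logLik -18884.37 on 13148 days; alpha = 0.2927, theta = -0.7078, h = 1.719

rate_ratio_ci(fit, seed = 42)
#> # A tibble: 1 × 7
#>       h ci_low ci_high peak_day level n_samples  seed
#>   <dbl>  <dbl>   <dbl>    <dbl> <dbl>     <dbl> <dbl>
#> 1  1.72   1.65    1.79     41.1  0.95     10000    42

cohort_e60(fit, cohort)
#> # A tibble: 1 × 7
#>   birth_year sex   e_observed e_model e_lower_bound contribution b_policy
#>        <dbl> <chr>      <dbl>   <dbl>         <dbl>        <dbl> <chr>
#> 1       1820 male        74.3    74.3          76.7         2.45 mean
```

Read: the fitted amplitude 0.293 (truth 0.3) implies winter mortality
1.72× summer mortality (95% CI 1.65–1.79), peaking on day 41 (second week
of February). Members lived 74.3 years on average — exactly what the
fitted model implies — and would have lived 76.7 years under the
lower-bound hazard, so seasonality cost this cohort 2.45 years of life
expectancy at 60.

For a whole study, `run_pipeline(records, 1800:1901)` maps these steps
over every (birth year, sex) cohort and returns tidy per-cohort tables
(`fits`, `seasonality`, `life_expectancy`, `summary`) plus a run manifest;
`plot_rate_ratio()`, `plot_e60()` and `plot_daily_rates()` draw the usual
figures. A thin CLI (`inst/cli/seasonmort.R`) exposes
`simulate` / `fit` / `report` subcommands.

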