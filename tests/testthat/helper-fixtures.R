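# Shared fixtures, built in code and cached for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

# truth used for the large recovery cohorts: (mu, beta, a1, a2)
recovery_truth <- function() {
  hazard_params(mu = 6e-5, beta = 2.4e-4, a1 = 0.2, a2 = 0.25)
}

# a single simulated male cohort at the recovery truth, as person records
recovery_study <- function(n, seed = 101, birth_year = 1820) {
  key <- sprintf("study_%d_%d_%d", n, seed, birth_year)
  if (is.null(.fixture_cache[[key]])) {
    p <- recovery_truth()
    sc <- scenario_config(birth_year, "male", n,
                          mu = p$mu, beta = p$beta,
                          alpha = p$alpha, theta = p$theta, seed = seed)
    .fixture_cache[[key]] <- generate_study(sc)
  }
  .fixture_cache[[key]]
}

recovery_cohort <- function(n, seed = 101, birth_year = 1820) {
  key <- sprintf("cohort_%d_%d_%d", n, seed, birth_year)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      build_cohort(recovery_study(n, seed, birth_year), birth_year, "male")
  }
  .fixture_cache[[key]]
}

recovery_fit <- function(n, seed = 101, birth_year = 1820) {
  key <- sprintf("fit_%d_%d_%d", n, seed, birth_year)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      fit_poisson(build_daily_counts(recovery_cohort(n, seed, birth_year)))
  }
  .fixture_cache[[key]]
}

# five hand-written person records; three satisfy the age-59 inclusion rule
# for the male 1800 cohort
toy_records <- function() {
  tibble::tibble(
    birth_date = as.Date(c("1800-06-01", "1800-02-13", "1800-12-31",
                           "1800-06-01", "1801-06-01")),
    death_date = as.Date(c("1860-03-01", "1875-07-04", "1860-01-01",
                           "1859-12-31", "1870-01-01")),
    sex = c("male", "male", "male", "male", "male")
  )
}

# independent daily-Bernoulli log-likelihood of the seasonal Gompertz model,
# written directly from the hazard definition (oracle path: no reuse of the
# fitting code's internals)
oracle_loglik <- function(par, td, b, censored, n_days) {
  w <- 2 * pi / 365.25
  ll <- 0
  for (i in seq_along(td)) {
    days <- 0:(if (censored[i]) n_days - 1L else td[i])
    lam <- exp(par[1] + par[2] * (days + 365 - b[i]) +
                 par[3] * sin(w * days) + par[4] * cos(w * days))
    if (censored[i]) {
      ll <- ll - sum(lam)
    } else {
      ll <- ll - sum(lam[-length(lam)]) + log(1 - exp(-lam[length(lam)]))
    }
  }
  ll
}
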