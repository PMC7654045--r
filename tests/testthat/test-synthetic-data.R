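test_that("simulated death days follow the discrete constant-hazard law", {
  p <- hazard_params(0.01, 0)
  sim <- simulate_person(p, b = 0, n = 1e5, seed = 9)
  # geometric death-day distribution (0-based): exact mean 1/(e^c - 1)
  expect_equal(mean(sim$t_death), 1 / expm1(0.01), tolerance = 0.01)
  expect_false(any(sim$capped))
  expect_equal(nrow(sim), 1e5)
})

test_that("seasonal simulation reproduces the model's winter excess", {
  p <- hazard_params_polar(6e-5, 2.4e-4, 0.35, -2 * pi * 41 / 365.25)
  sim <- simulate_person(p, b = sample(0:364, 2e5, replace = TRUE),
                         n = 2e5, seed = 17)
  # winter-month deaths exceed summer-month deaths
  doy <- (sim$t_death) %% 365.25
  winter <- sum(doy < 60 | doy > 330)   # ~Dec-Feb window
  summer <- sum(doy > 150 & doy < 240)  # ~Jun-Aug window
  expect_gt(winter, summer)

  # empirical monthly peak-to-trough death-rate ratio tracks the rate ratio
  month <- floor((doy %% 365.25) / 30.4375)
  rates <- tabulate(month + 1, nbins = 12)
  emp_ratio <- max(rates) / min(rates)
  expect_equal(emp_ratio, rate_ratio(p), tolerance = 0.1)
})

test_that("without seasonality the death day-of-year is near-uniform", {
  p <- hazard_params(5e-5, 0)  # no growth, no seasonality
  ok <- 0L
  for (r in 1:3) {
    sim <- simulate_person(p, b = 0, n = 4000, seed = 40 + r)
    sim <- sim[!sim$capped, ]  # survivors past the age cap sit on one day
    doy <- floor(sim$t_death %% 365.25)
    counts <- tabulate(floor(doy / 30.4375) + 1, nbins = 12)
    ok <- ok + (stats::chisq.test(counts)$p.value > 0.01)
  }
  expect_gte(ok, 2L)
})

test_that("generate_study is deterministic with per-cohort substreams", {
  sc <- scenario_config(c(1820, 1880), "female", 1000,
                        mu = 6e-5, beta = 2.4e-4, alpha = 0.25, theta = -0.7,
                        seed = 33)
  s1 <- generate_study(sc)
  s2 <- generate_study(sc)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2000L)
  expect_true(all(s1$sex == "female"))
  # generating only the 1880 cohort reproduces its rows exactly
  sc80 <- scenario_config(1880, "female", 1000,
                          mu = 6e-5, beta = 2.4e-4, alpha = 0.25, theta = -0.7,
                          seed = 33)
  expect_identical(generate_study(sc80),
                   dplyr::filter(s1, format(birth_date, "%Y") == "1880"))
  # all emitted persons satisfy the inclusion rule by construction
  expect_true(all(s1$death_date >=
                    as.Date(sprintf("%s-01-01",
                                    as.integer(format(s1$birth_date, "%Y")) + 60))))
})

test_that("scenario trajectories validate and expand per sex", {
  sc <- default_scenario(birth_years = c(1800, 1901), cohort_size = 10)
  expect_equal(nrow(sc), 4L)
  expect_true(all(sc$mu > 0 & sc$alpha >= 0))
  # female amplitude exceeds male early on; both decline across cohorts
  first <- dplyr::filter(sc, birth_year == 1800)
  expect_gt(first$alpha[first$sex == "female"],
            first$alpha[first$sex == "male"])
  expect_lt(dplyr::filter(sc, birth_year == 1901, sex == "male")$alpha,
            dplyr::filter(sc, birth_year == 1800, sex == "male")$alpha)
  expect_error(scenario_config(1800, "male", 10, mu = -1, beta = 1e-4,
                               alpha = 0, theta = 0), "mu > 0")
})

test_that("a declining-amplitude study propagates through the pipeline", {
  years <- c(1810, 1850, 1890)
  sc <- scenario_config(years, "male", 15000,
                        mu = function(y) 4e-5 * exp(0.35 - 0.003 * (y - 1810)),
                        beta = 2.4e-4,
                        alpha = function(y) 0.35 - 0.003 * (y - 1810),
                        theta = -0.7, seed = 71)
  run <- run_pipeline(generate_study(sc), years, sexes = "male",
                      ci_samples = 1000, seed = 5)
  expect_equal(nrow(run$summary), 3L)
  expect_true(all(diff(run$summary$h) < 0))
  expect_true(all(diff(run$summary$contribution) < 0))
})

test_that("fixed amplitude and scale give a flat seasonality contribution", {
  years <- c(1810, 1850, 1890)
  sc <- scenario_config(years, "male", 40000,
                        mu = 4e-5 * exp(0.2), beta = 2.4e-4,
                        alpha = 0.2, theta = -0.7, seed = 77)
  run <- run_pipeline(generate_study(sc), years, sexes = "male",
                      ci_samples = 500, seed = 5)
  expect_lt(max(run$summary$contribution) - min(run$summary$contribution), 0.4)
})
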