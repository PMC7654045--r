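test_that("hazard_rate matches the closed form along an independent path", {
  expect_equal(hazard_rate(hazard_params(1e-4, 0), t = 123, b = 50), 1e-4)
  p2 <- hazard_params_polar(1e-4, 0, alpha = log(2), theta = 0)
  expect_equal(hazard_rate(p2, t = 0, b = 0), 2e-4)
  # polar evaluation vs independent linear-form evaluation
  w <- 2 * pi / 365.25
  set.seed(42)
  for (i in 1:20) {
    a1 <- runif(1, -0.5, 0.5); a2 <- runif(1, -0.5, 0.5)
    mu <- runif(1, 1e-5, 1e-3); beta <- runif(1, 0, 5e-4)
    t <- runif(1, 0, 13000); b <- runif(1, 0, 365)
    expect_equal(hazard_rate(hazard_params(mu, beta, a1, a2), t, b),
                 mu * exp(beta * (t + 365 - b)) *
                   exp(a1 * sin(w * t) + a2 * cos(w * t)),
                 tolerance = 1e-12)
  }
  p <- hazard_params_polar(5e-5, 2.4e-4, 0.3, 2.4)
  expect_equal(hazard_rate(p, 1000, 180),
               5e-5 * exp(2.4e-4 * (1000 + 365 - 180)) *
                 exp(0.3 * cos(w * 1000 + 2.4)),
               tolerance = 1e-12)
  expect_error(hazard_rate(hazard_params(1e-4, -1e-4), 0, 0), "non-negative")
  expect_error(hazard_params(-1e-4, 2e-4), "positive")
})

test_that("to_polar is the quadrant-aware amplitude/phase transform", {
  expect_equal(to_polar(0, 1), list(alpha = 1, theta = 0, degenerate = FALSE))
  p <- to_polar(-1, 0)
  expect_equal(p$alpha, 1)
  expect_equal(p$theta, pi / 2)
  d <- to_polar(0, 0)
  expect_true(d$degenerate)
  expect_equal(d$theta, 0)
  # round trip: reconstructed sinusoid matches pointwise over a year
  w <- 2 * pi / 365.25
  tg <- 0:364
  set.seed(7)
  for (i in 1:20) {
    a1 <- runif(1, -1, 1); a2 <- runif(1, -1, 1)
    pp <- to_polar(a1, a2)
    expect_equal(pp$alpha * cos(w * tg + pp$theta),
                 a1 * sin(w * tg) + a2 * cos(w * tg), tolerance = 1e-12)
    expect_equal(c(-pp$alpha * sin(pp$theta), pp$alpha * cos(pp$theta)),
                 c(a1, a2), tolerance = 1e-12)
  }
})

test_that("Poisson regression recovers generating parameters", {
  truth <- recovery_truth()
  fit <- recovery_fit(20000)
  expect_true(fit$converged)
  est <- tidy(fit)
  true_vec <- c(NA, truth$beta, truth$a1, truth$a2)
  z <- abs(est$estimate[-1] - true_vec[-1]) / est$std.error[-1]
  expect_true(all(z < 3))
  # seasonal terms jointly highly significant on seasonal data
  expect_lt(fit$lrt_seasonal$p.value, 0.001)
})

test_that("null data yield no spurious seasonality or growth", {
  # counts simulated straight from the constant-rate Poisson law
  set.seed(11)
  n_days <- 1500; N <- rep(50000L, n_days); rate <- 2e-4
  reps <- 40
  reject <- logical(reps); beta_ok <- logical(reps); alpha_hat <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- rpois(n_days, N * rate)
    dc <- tibble::tibble(t = 0:(n_days - 1L), N = N, d = d)
    fit <- fit_poisson(dc)
    reject[r] <- fit$lrt_seasonal$p.value < 0.05
    beta_ok[r] <- abs(fit$params$beta) < 3 * sqrt(fit$vcov["beta", "beta"])
    alpha_hat[r] <- fit$params$alpha
  }
  # type-I error of the seasonality test near nominal
  expect_lte(sum(reject), 8)
  expect_gte(sum(beta_ok), reps - 2)
  # under the null, alpha_hat is the norm of two ~N(0, se^2) coefficients,
  # so its median sits near 1.18 * se; assert it stays on that noise scale
  se_a <- sqrt(2 / (n_days * 50000 * rate))
  expect_lt(median(alpha_hat), 3 * se_a)
})

test_that("direct ML agrees with Poisson regression and beats the truth", {
  truth <- recovery_truth()
  small <- 4000; large <- 20000
  gap <- function(n) {
    fp <- recovery_fit(n)
    fd <- fit_direct_ml(recovery_cohort(n))
    expect_true(fd$converged)
    max(abs(c(fd$params$beta / fp$params$beta,
              fd$params$a1 / fp$params$a1,
              fd$params$a2 / fp$params$a2) - 1))
  }
  g_small <- gap(small); g_large <- gap(large)
  expect_lt(g_small, 0.01)
  expect_lt(g_large, 0.01)
  # approximation gap does not grow with cohort size (noise margin 0.3%)
  expect_lt(g_large, g_small + 0.003)

  # MLE property: optimised exact likelihood is at least the likelihood at
  # the true parameters, evaluated by an independent implementation
  co <- recovery_cohort(1000, seed = 31)
  fd <- fit_direct_ml(co)
  t0 <- attr(co, "t0")
  grid_end <- as.Date(sprintf("%d-12-31", attr(co, "birth_year") + 95))
  n_days <- as.integer(grid_end - t0) + 1L
  td <- as.integer(co$death_date - t0)
  cens <- td >= n_days
  ll_true <- oracle_loglik(c(log(truth$mu), truth$beta, truth$a1, truth$a2),
                           td, attr(co, "b"), cens, n_days)
  expect_gte(fd$loglik, ll_true)
  # and the optimum value itself matches the oracle likelihood evaluation
  ll_hat <- oracle_loglik(c(fd$intercept, fd$params$beta, fd$params$a1,
                            fd$params$a2), td, attr(co, "b"), cens, n_days)
  expect_equal(fd$loglik, ll_hat, tolerance = 1e-8)
})

test_that("constant-hazard MLE of the daily likelihood has its closed form", {
  # one person, no growth, no seasonality: death on day t gives
  # L(lam) = exp(-lam * t) * (1 - exp(-lam)), maximised at -log(t / (t + 1))
  t_death <- 999L
  nll1 <- function(lam) lam * t_death - log(1 - exp(-lam))
  opt <- optimize(nll1, c(1e-6, 1e-1), tol = 1e-10)
  expect_equal(opt$minimum, -log(t_death / (t_death + 1)), tolerance = 1e-6)
  # which is the continuous exponential MLE 1/lifetime to first order
  expect_equal(opt$minimum, 1 / (t_death + 0.5), tolerance = 1e-3)
})

test_that("standard errors shrink like 1/sqrt(cohort size)", {
  se <- function(n) sqrt(diag(recovery_fit(n)$vcov))[-1]
  ratio <- se(4000) / se(20000)
  expect_true(all(abs(ratio / sqrt(20000 / 4000) - 1) < 0.2))
})

test_that("degenerate counts are rejected", {
  dc <- tibble::tibble(t = 0:99, N = rep(100L, 100), d = rep(0L, 100))
  expect_error(fit_poisson(dc), "identifiable")
})
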