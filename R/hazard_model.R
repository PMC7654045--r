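#' Hazard model parameters
#'
#' Parameter set of the seasonal Gompertz hazard
#' \deqn{\lambda(t \mid b) = \mu\, e^{\beta (t + 365 - b)}\,
#'   e^{\alpha \cos(2\pi t / 365.25 + \theta)},}
#' where `t` is follow-up time in days, `b` the birth day of year, `mu` the
#' baseline scale (per day), `beta` the exponential (Gompertz) growth rate
#' (per day), and the seasonal modulation is carried either by the linear
#' pair `(a1, a2)` (sine/cosine coefficients) or by the polar pair
#' `(alpha, theta)` with `alpha = sqrt(a1^2 + a2^2)` and
#' `theta = atan2(-a1, a2)`.
#'
#' @param mu baseline hazard scale, per day; > 0.
#' @param beta Gompertz growth rate, per day; >= 0.
#' @param a1,a2 sine and cosine coefficients on the log-hazard scale.
#' @return object of class `hazard_params` (a named list with `mu`, `beta`,
#'   `a1`, `a2` and the derived `alpha`, `theta`).
#' @export
hazard_params <- function(mu, beta, a1 = 0, a2 = 0) {
  if (!is.finite(mu) || mu <= 0) stop("`mu` must be a positive rate")
  # the model assumes beta > 0, but estimates from null-like data may sit
  # marginally below zero; hazard_rate() enforces positivity at evaluation
  if (!is.finite(beta)) stop("`beta` must be finite")
  polar <- to_polar(a1, a2)
  structure(list(mu = mu, beta = beta, a1 = a1, a2 = a2,
                 alpha = polar$alpha, theta = polar$theta),
            class = "hazard_params")
}

#' Build hazard parameters from amplitude and phase
#'
#' @param mu,beta as in [hazard_params()].
#' @param alpha seasonal amplitude on the log-hazard scale; >= 0.
#' @param theta phase of the cosine modulation, radians.
#' @export
hazard_params_polar <- function(mu, beta, alpha = 0, theta = 0) {
  if (alpha < 0) stop("`alpha` must be non-negative")
  hazard_params(mu, beta, a1 = -alpha * sin(theta), a2 = alpha * cos(theta))
}

#' @export
print.hazard_params <- function(x, ...) {
  cat(sprintf(
    "<hazard_params> mu = %.4g/day, beta = %.4g/day, alpha = %.4g, theta = %.4g rad\n",
    x$mu, x$beta, x$alpha, x$theta))
  invisible(x)
}

#' Seasonal Gompertz hazard rate
#'
#' Evaluates the per-day mortality rate of the seasonal Gompertz model for a
#' person born on day of year `b`, at follow-up day `t` (day 0 = January 1 of
#' the year of the 60th birthday, so age in days is `t + 365 - b` past the
#' 59th birthday).
#'
#' @param params a `hazard_params` object.
#' @param t follow-up time, days (vectorised).
#' @param b birth day of year (0..365).
#' @return per-day hazard, strictly positive.
#' @export
hazard_rate <- function(params, t, b = 0) {
  stopifnot(inherits(params, "hazard_params"))
  if (params$beta < 0) stop("`beta` must be non-negative")
  params$mu * exp(params$beta * (t + 365 - b)) *
    exp(params$alpha * cos(OMEGA * t + params$theta))
}

#' Convert sine/cosine coefficients to amplitude and phase
#'
#' The sinusoidal log-hazard term `a1 sin(wt) + a2 cos(wt)` equals
#' `alpha cos(wt + theta)` with `alpha = sqrt(a1^2 + a2^2)` and `theta`
#' the quadrant-aware angle `atan2(-a1, a2)` in (-pi, pi], so that
#' `a2 = alpha cos(theta)` and `a1 = -alpha sin(theta)`.
#'
#' @param a1,a2 sine and cosine coefficients.
#' @return list with `alpha`, `theta`, and `degenerate` (TRUE when
#'   `a1 = a2 = 0`, where the phase is undefined and returned as 0).
#' @export
to_polar <- function(a1, a2) {
  alpha <- sqrt(a1^2 + a2^2)
  degenerate <- alpha == 0
  theta <- ifelse(degenerate, 0, atan2(-a1, a2))
  list(alpha = alpha, theta = theta, degenerate = degenerate)
}

#' Fit the seasonal Gompertz hazard by Poisson regression
#'
#' Fits the piecewise-exponential (daily) approximation of the seasonal
#' Gompertz model: daily death counts are treated as Poisson with
#' \deqn{\log E(d_t) = \log N_t + \mu + \beta t + a_1 \sin(2\pi t/365.25)
#'   + a_2 \cos(2\pi t/365.25),}
#' estimated by [stats::glm()] with a log risk-set offset. The intercept
#' absorbs the cohort-average age offset `365 - b`; `mu` reported in the
#' parameters is `exp(intercept)`. Days with an empty risk set are dropped
#' (the offset is undefined there).
#'
#' @param daily_counts tibble from [build_daily_counts()] (columns `t`, `N`,
#'   `d`).
#' @return a `hazard_fit`: list with `params` (`hazard_params`), `vcov`
#'   (4x4 over intercept, beta, a1, a2), `loglik`, `n_days`, `converged`,
#'   `lrt_seasonal` (likelihood-ratio test of `a1 = a2 = 0`), `method`, plus
#'   cohort metadata carried from the input.
#' @export
fit_poisson <- function(daily_counts) {
  dat <- dplyr::filter(tibble::as_tibble(daily_counts), .data$N > 0)
  if (sum(dat$d) == 0) stop("all death counts are zero: model not identifiable")
  dat$s <- sin(OMEGA * dat$t)
  dat$c <- cos(OMEGA * dat$t)
  fit <- glm(d ~ t + s + c, family = poisson(), data = dat,
             offset = log(dat$N), control = list(epsilon = 1e-10, maxit = 100))
  fit0 <- glm(d ~ t, family = poisson(), data = dat,
              offset = log(dat$N), control = list(epsilon = 1e-10, maxit = 100))
  cf <- coef(fit)
  lrt_stat <- as.numeric(2 * (logLik(fit) - logLik(fit0)))
  new_hazard_fit(
    intercept = unname(cf[1]),
    beta = unname(cf["t"]), a1 = unname(cf["s"]), a2 = unname(cf["c"]),
    vcov = unname(vcov(fit)),
    loglik = as.numeric(logLik(fit)),
    n_days = nrow(dat),
    converged = isTRUE(fit$converged),
    lrt_seasonal = list(statistic = lrt_stat, df = 2,
                        p.value = pchisq(lrt_stat, df = 2, lower.tail = FALSE)),
    method = "poisson",
    meta = daily_counts_meta(daily_counts)
  )
}

daily_counts_meta <- function(x) {
  list(birth_year = attr(x, "birth_year"), sex = attr(x, "sex"),
       b_mean = attr(x, "b_mean"), n0 = attr(x, "n0"),
       n_censored = attr(x, "n_censored"))
}

new_hazard_fit <- function(intercept, beta, a1, a2, vcov, loglik, n_days,
                           converged, lrt_seasonal = NULL, method, meta = list()) {
  dimnames(vcov) <- list(c("intercept", "beta", "a1", "a2"),
                         c("intercept", "beta", "a1", "a2"))
  structure(list(
    params = hazard_params(exp(intercept), beta, a1, a2),
    intercept = intercept,
    vcov = vcov,
    loglik = loglik,
    n_days = n_days,
    converged = converged,
    lrt_seasonal = lrt_seasonal,
    method = method,
    meta = meta
  ), class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  m <- x$meta
  id <- if (!is.null(m$birth_year)) sprintf(" [%s %s]", m$sex, m$birth_year) else ""
  cat(sprintf("<hazard_fit:%s>%s\n", x$method, id))
  print(tidy(x))
  cat(sprintf("logLik %.2f on %d days; alpha = %.4f, theta = %.4f, h = %.3f\n",
              x$loglik, x$n_days, x$params$alpha, x$params$theta,
              rate_ratio(x$params)))
  invisible(x)
}

#' @rdname fit_poisson
#' @param x a `hazard_fit`.
#' @param ... unused.
#' @method tidy hazard_fit
#' @export
tidy.hazard_fit <- function(x, ...) {
  est <- c(x$intercept, x$params$beta, x$params$a1, x$params$a2)
  tibble::tibble(
    term = c("intercept", "beta", "a1", "a2"),
    estimate = est,
    std.error = sqrt(diag(x$vcov))
  )
}

#' @rdname fit_poisson
#' @method glance hazard_fit
#' @export
glance.hazard_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$params$mu, beta = x$params$beta,
    a1 = x$params$a1, a2 = x$params$a2,
    alpha = x$params$alpha, theta = x$params$theta,
    logLik = x$loglik, n_days = x$n_days,
    converged = x$converged, method = x$method
  )
}

#' Fit the seasonal Gompertz hazard by direct maximum likelihood
#'
#' Maximises the exact person-level survival likelihood of the seasonal
#' Gompertz model with per-individual age offsets `365 - b_i` and a
#' piecewise-constant daily hazard: a member dying on follow-up day `t`
#' contributes survival through days `0..t-1` and a within-day death
#' probability `1 - exp(-lambda(t | b_i))`; members dying after the grid end
#' contribute survival only (right-censoring). This is the estimator that the
#' Poisson regression of [fit_poisson()] approximates; the two agree closely
#' on large cohorts.
#'
#' @param cohort a `cohort` from [build_cohort()].
#' @param end_age_year last age year of follow-up (default 95).
#' @param start optional starting values; by default taken from
#'   [fit_poisson()] on the aggregated counts.
#' @return a `hazard_fit` (same shape as [fit_poisson()]); the reported
#'   `intercept` is `log(mu)` of the person-level model (not the
#'   cohort-aggregated intercept).
#' @export
fit_direct_ml <- function(cohort, end_age_year = 95, start = NULL) {
  t0 <- attr(cohort, "t0")
  birth_year <- attr(cohort, "birth_year")
  grid_end <- as.Date(sprintf("%d-12-31", birth_year + end_age_year))
  n_days <- as.integer(grid_end - t0) + 1L
  td <- as.integer(cohort$death_date - t0)
  b <- attr(cohort, "b")
  died <- td < n_days
  tg <- 0:(n_days - 1L)
  sg <- sin(OMEGA * tg); cg <- cos(OMEGA * tg)

  tdd <- td[died]; bd <- b[died]; bc <- b[!died]

  # negative log-likelihood in (log mu, beta, a1, a2)
  nll <- function(par) {
    lam0 <- exp(par[1] + par[2] * (tg + 365) + par[3] * sg + par[4] * cg)
    cum0 <- c(0, cumsum(lam0))          # cum0[t+1] = sum_{s<t} lam0(s)
    off <- exp(-par[2] * b)
    ll_cens <- -off[!died] * cum0[n_days + 1L]
    lam_i <- lam0[tdd + 1L] * off[died]
    ll_died <- -off[died] * cum0[tdd + 1L] + log(-expm1(-lam_i))
    -(sum(ll_cens) + sum(ll_died))
  }
  gr <- function(par) {
    lam0 <- exp(par[1] + par[2] * (tg + 365) + par[3] * sg + par[4] * cg)
    cum0 <- c(0, cumsum(lam0))
    cumb <- c(0, cumsum(lam0 * (tg + 365)))
    cums <- c(0, cumsum(lam0 * sg))
    cumc <- c(0, cumsum(lam0 * cg))
    offd <- exp(-par[2] * bd); offc <- exp(-par[2] * bc)
    lam_i <- lam0[tdd + 1L] * offd
    # d/dpar of -log(1 - exp(-lam_i)) = -dlam_i/dpar / (exp(lam_i) - 1)
    w <- 1 / expm1(lam_i)
    iT <- n_days + 1L; id <- tdd + 1L
    g_lmu <- sum(offc * cum0[iT]) + sum(offd * cum0[id]) - sum(w * lam_i)
    g_beta <- sum(offc * (cumb[iT] - bc * cum0[iT])) +
      sum(offd * (cumb[id] - bd * cum0[id])) -
      sum(w * lam_i * (tdd + 365 - bd))
    g_a1 <- sum(offc * cums[iT]) + sum(offd * cums[id]) -
      sum(w * lam_i * sg[id])
    g_a2 <- sum(offc * cumc[iT]) + sum(offd * cumc[id]) -
      sum(w * lam_i * cg[id])
    c(g_lmu, g_beta, g_a1, g_a2)
  }

  if (is.null(start)) {
    pf <- fit_poisson(build_daily_counts(cohort, end_age_year))
    start <- c(pf$intercept - pf$params$beta * (365 - mean(b)),
               pf$params$beta, pf$params$a1, pf$params$a2)
  }
  opt <- optim(start, nll, gr, method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-14, maxit = 1000,
                              parscale = c(1, 1e-4, 0.1, 0.1),
                              ndeps = c(1e-7, 1e-10, 1e-7, 1e-7)))
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, 4, 4)
  })
  new_hazard_fit(
    intercept = opt$par[1], beta = opt$par[2], a1 = opt$par[3], a2 = opt$par[4],
    vcov = vc, loglik = -opt$value, n_days = n_days,
    converged = opt$convergence == 0L,
    method = "direct_ml",
    meta = list(birth_year = birth_year, sex = attr(cohort, "sex"),
                b_mean = mean(b), n0 = nrow(cohort), n_censored = sum(!died))
  )
}
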