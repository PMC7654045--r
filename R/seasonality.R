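#' Winter/summer mortality rate ratio
#'
#' The within-year ratio of the highest to the lowest mortality rate implied
#' by the seasonal Gompertz model:
#' \deqn{h = e^{2\alpha - 182.625\,\beta}.}
#' The peak sits at the top of the cosine modulation and the trough half a
#' model year (182.625 days) later, by which time the age drift has raised
#' the baseline by `exp(182.625 beta)` — hence the second term. `h` can be
#' read as how many times higher the risk of dying is in winter than in
#' summer; it is constant within a cohort under this model.
#'
#' @param params a `hazard_params` object (or a `hazard_fit`, whose
#'   parameters are used).
#' @return the dimensionless rate ratio, > 0.
#' @export
rate_ratio <- function(params) {
  if (inherits(params, "hazard_fit")) params <- params$params
  stopifnot(inherits(params, "hazard_params"))
  exp(2 * params$alpha - half_year() * params$beta)
}

#' Parametric-bootstrap confidence interval for the rate ratio
#'
#' Samples `(beta, a1, a2)` from a multivariate normal distribution with mean
#' and covariance taken from the fit (the intercept is marginalised out),
#' maps each draw through the amplitude transform and the rate-ratio formula,
#' and returns percentiles of the empirical distribution.
#'
#' @param fit a `hazard_fit`.
#' @param level confidence level (default 0.95).
#' @param n_samples number of multivariate-normal draws.
#' @param seed integer seed; every call with the same fit and seed returns
#'   identical bounds.
#' @return tibble with one row: `h`, `ci_low`, `ci_high`, `peak_day`,
#'   `level`, `n_samples`, `seed`.
#' @export
rate_ratio_ci <- function(fit, level = 0.95, n_samples = 10000, seed = 1L) {
  stopifnot(inherits(fit, "hazard_fit"))
  idx <- c("beta", "a1", "a2")
  mu <- c(fit$params$beta, fit$params$a1, fit$params$a2)
  sigma <- fit$vcov[idx, idx]
  if (any(!is.finite(sigma))) stop("fit covariance is not available")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1e-300)) {
    stop("fit covariance is not positive semi-definite")
  }
  draws <- withr_seed(seed, MASS::mvrnorm(n_samples, mu = mu, Sigma = sigma))
  h <- exp(2 * sqrt(draws[, 2]^2 + draws[, 3]^2) - half_year() * draws[, 1])
  qs <- quantile(h, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE)
  tibble::tibble(
    h = rate_ratio(fit$params),
    ci_low = qs[1], ci_high = qs[2],
    peak_day = peak_day(fit$params$theta),
    level = level, n_samples = n_samples, seed = seed
  )
}

# run code with a temporary RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Calendar day of the seasonal mortality peak
#'
#' The day of year (counted from January 1 = 0) at which the cosine
#' modulation attains its maximum: `(-theta / omega) mod 365.25` with
#' `omega = 2 pi / 365.25`. A February peak corresponds to `theta` near
#' `-2 pi * 41 / 365.25`.
#'
#' @param theta phase in (-pi, pi].
#' @param alpha optional amplitude; when 0 the peak day is undefined and `NA`
#'   is returned with a warning.
#' @return day of year in [0, 365.25).
#' @export
peak_day <- function(theta, alpha = NULL) {
  if (!is.null(alpha) && any(alpha == 0)) {
    warning("peak day is undefined when the seasonal amplitude is zero")
    out <- (-theta * 365.25 / (2 * pi)) %% 365.25
    out[alpha == 0] <- NA_real_
    return(out)
  }
  (-theta * 365.25 / (2 * pi)) %% 365.25
}

#' Per-cohort seasonality summary
#'
#' Convenience wrapper pairing the cohort identifier with [rate_ratio_ci()].
#'
#' @inheritParams rate_ratio_ci
#' @return one-row tibble: `birth_year`, `sex`, `h`, `ci_low`, `ci_high`,
#'   `peak_day`, `level`, `n_samples`, `seed`.
#' @export
seasonality_summary <- function(fit, level = 0.95, n_samples = 10000, seed = 1L) {
  dplyr::bind_cols(
    tibble::tibble(birth_year = fit$meta$birth_year %||% NA_integer_,
                   sex = fit$meta$sex %||% NA_character_),
    rate_ratio_ci(fit, level = level, n_samples = n_samples, seed = seed)
  )
}
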