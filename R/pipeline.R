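#' Centered running mean
#'
#' The visualization smoother: each point is replaced by the local mean of
#' the `width` surrounding points. For even widths the window is made
#' symmetric by spanning `width + 1` points with half weight on the two end
#' points (the standard centred moving average of even order), which leaves
#' linear trends unchanged in the interior. At the series edges the window is
#' truncated to the available points.
#'
#' @param x numeric series.
#' @param width window width in points (default 60, i.e. days).
#' @return smoothed series of the same length.
#' @export
running_mean <- function(x, width = 60) {
  if (length(x) == 0) stop("empty series")
  stopifnot(width >= 1)
  w <- if (width %% 2 == 0) c(0.5, rep(1, width - 1), 0.5) else rep(1, width)
  num <- as.numeric(stats::filter(c(rep(0, length(w)), x, rep(0, length(w))),
                                  w, sides = 2))
  den <- as.numeric(stats::filter(c(rep(0, length(w)), rep(1, length(x)),
                                    rep(0, length(w))), w, sides = 2))
  i <- length(w) + seq_along(x)
  num[i] / den[i]
}

#' Run the full cohort seasonality pipeline
#'
#' One call from person-level records to per-cohort results: for each
#' (birth year, sex) cohort, applies the inclusion rule, builds daily counts,
#' fits the seasonal Gompertz hazard by Poisson regression, summarises
#' seasonality (rate ratio with bootstrap CI, peak day) and computes actual
#' and counterfactual life expectancy at 60. Cohorts whose fit fails are
#' logged and skipped; they appear in the manifest, never abort the run.
#'
#' @param records person-level tibble (`birth_date`, `death_date`, `sex`).
#' @param birth_years cohort birth years to analyse.
#' @param sexes subset of `c("female", "male")`.
#' @param end_age_year last age year of follow-up (default 95).
#' @param ci_level,ci_samples confidence level and bootstrap draw count.
#' @param seed integer seed for the bootstrap (per-cohort substreams derived
#'   from it).
#' @param b_policy birth-day policy for the age conversion (see
#'   [cohort_e60()]).
#' @param out_dir optional directory; when given, writes `fits.csv`,
#'   `seasonality.csv`, `life_expectancy.csv`, `summary.csv` and
#'   `manifest.json` there.
#' @return a `seasons_run`: list with tibbles `fits`, `seasonality`,
#'   `life_expectancy`, `summary` and a `manifest` list.
#' @export
run_pipeline <- function(records, birth_years, sexes = c("female", "male"),
                         end_age_year = 95, ci_level = 0.95,
                         ci_samples = 10000, seed = 1L,
                         b_policy = "mean", out_dir = NULL) {
  grid <- tidyr::expand_grid(birth_year = sort(unique(birth_years)),
                             sex = sexes)
  failures <- list()
  rows <- purrr::pmap(grid, function(birth_year, sex) {
    tryCatch({
      cohort <- build_cohort(records, birth_year, sex)
      if (nrow(cohort) == 0L) stop("empty cohort")
      counts <- build_daily_counts(cohort, end_age_year)
      fit <- fit_poisson(counts)
      seas <- seasonality_summary(fit, level = ci_level,
                                  n_samples = ci_samples,
                                  seed = cohort_seed(seed, birth_year, sex))
      le <- cohort_e60(fit, cohort, b_policy = b_policy)
      list(fit = dplyr::bind_cols(
             tibble::tibble(birth_year = birth_year, sex = sex,
                            n0 = attr(counts, "n0"),
                            n_deaths = sum(counts$d),
                            n_censored = attr(counts, "n_censored"),
                            b_mean = attr(counts, "b_mean")),
             glance(fit),
             tibble::tibble(
               se_beta = sqrt(fit$vcov["beta", "beta"]),
               se_a1 = sqrt(fit$vcov["a1", "a1"]),
               se_a2 = sqrt(fit$vcov["a2", "a2"]),
               p_seasonal = fit$lrt_seasonal$p.value)),
           seas = seas, le = le)
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<-
        list(birth_year = birth_year, sex = sex,
             message = conditionMessage(e))
      message("cohort ", birth_year, " ", sex, " failed: ",
              conditionMessage(e))
      NULL
    })
  })
  rows <- purrr::compact(rows)
  fits <- purrr::map_dfr(rows, "fit")
  seasonality <- purrr::map_dfr(rows, "seas")
  life_expectancy <- purrr::map_dfr(rows, "le")
  summary <- fits |>
    dplyr::select("birth_year", "sex", "n0", "n_deaths", "n_censored",
                  "alpha", "beta", "theta") |>
    dplyr::left_join(dplyr::select(seasonality, "birth_year", "sex", "h",
                                   "ci_low", "ci_high", "peak_day"),
                     by = c("birth_year", "sex")) |>
    dplyr::left_join(dplyr::select(life_expectancy, "birth_year", "sex",
                                   "e_observed", "e_model", "e_lower_bound",
                                   "contribution"),
                     by = c("birth_year", "sex"))
  manifest <- list(
    config = list(birth_years = range(birth_years), sexes = sexes,
                  end_age_year = end_age_year, ci_level = ci_level,
                  ci_samples = ci_samples, seed = seed, b_policy = b_policy),
    n_records_in = nrow(records),
    n_cohorts_fitted = nrow(fits),
    n_cohorts_failed = length(failures),
    failures = failures,
    row_counts = list(fits = nrow(fits), seasonality = nrow(seasonality),
                      life_expectancy = nrow(life_expectancy)),
    versions = list(seasonmort = as.character(utils::packageVersion("seasonmort")),
                    R = R.version.string)
  )
  out <- structure(list(fits = fits, seasonality = seasonality,
                        life_expectancy = life_expectancy,
                        summary = summary, manifest = manifest),
                   class = "seasons_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' Write pipeline outputs to a directory
#'
#' @param run a `seasons_run` from [run_pipeline()].
#' @param out_dir directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$fits, file.path(out_dir, "fits.csv"))
  readr::write_csv(run$seasonality, file.path(out_dir, "seasonality.csv"))
  readr::write_csv(run$life_expectancy, file.path(out_dir, "life_expectancy.csv"))
  readr::write_csv(run$summary, file.path(out_dir, "summary.csv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.seasons_run <- function(x, ...) {
  cat(sprintf("<seasons_run> %d cohorts fitted, %d failed\n",
              x$manifest$n_cohorts_fitted, x$manifest$n_cohorts_failed))
  print(x$summary)
  invisible(x)
}

#' Plot smoothed daily mortality rates with the model overlay
#'
#' Daily rates `d/N` smoothed by the 60-day running mean, with the fitted
#' hazard drawn on top.
#'
#' @param daily_counts tibble from [build_daily_counts()].
#' @param fit optional `hazard_fit` for the overlay.
#' @param width smoother width, days.
#' @return a ggplot.
#' @export
plot_daily_rates <- function(daily_counts, fit = NULL, width = 60) {
  dat <- dplyr::filter(tibble::as_tibble(daily_counts), .data$N > 0) |>
    dplyr::mutate(rate = running_mean(.data$d / .data$N, width))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$date, y = .data$rate)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "mortality rate (per day)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    dat$model <- exp(fit$intercept + fit$params$beta * dat$t +
                       fit$params$a1 * sin(OMEGA * dat$t) +
                       fit$params$a2 * cos(OMEGA * dat$t))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$model), data = dat,
                                colour = "magenta")
  }
  p
}

#' Plot rate-ratio trajectories with confidence bands
#'
#' @param seasonality per-cohort seasonality tibble (from a `seasons_run`).
#' @return a ggplot of `h` against birth year by sex, with CI ribbons.
#' @export
plot_rate_ratio <- function(seasonality) {
  ggplot2::ggplot(seasonality,
                  ggplot2::aes(x = .data$birth_year, y = .data$h,
                               colour = .data$sex, fill = .data$sex)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "birth year", y = "winter/summer mortality rate ratio") +
    ggplot2::theme_minimal()
}

#' Plot life expectancy at 60: observed, model, and lower bound
#'
#' @param life_expectancy per-cohort life-expectancy tibble (from a
#'   `seasons_run`).
#' @return a ggplot.
#' @export
plot_e60 <- function(life_expectancy) {
  long <- tidyr::pivot_longer(life_expectancy,
                              c("e_observed", "e_model", "e_lower_bound"),
                              names_to = "quantity", values_to = "years")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$birth_year, y = .data$years,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "birth year", y = "life expectancy at 60 (years of age)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_rate_ratio
#' @param object a `seasons_run`.
#' @param ... unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot seasons_run
#' @export
autoplot.seasons_run <- function(object, ...) {
  plot_rate_ratio(object$seasonality)
}
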