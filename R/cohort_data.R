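#' Day of year, counted from January 1 = 0
#'
#' Expresses a calendar date as the number of days elapsed since the beginning
#' of its year, the convention used for the birth day `b` throughout the
#' package (so `b` ranges over 0..364, or 0..365 in leap years).
#'
#' @param date a `Date` vector (or something coercible via [as.Date()]).
#' @return integer vector; January 1 maps to 0.
#' @examples
#' day_of_year(as.Date("1871-02-13")) # 43
#' @export
day_of_year <- function(date) {
  date <- as.Date(date)
  if (anyNA(date)) stop("`date` contains values that do not parse as calendar dates")
  as.POSIXlt(date)$yday
}

#' Read person-level records from a delimited text file
#'
#' Reads a CSV/TSV file (delimiter sniffed from the header line) holding one
#' row per person with a birth date, a death date and a sex code. Dates may be
#' ISO-8601 (`YYYY-MM-DD`) or compact (`YYYYMMDD`). Rows whose dates do not
#' parse, or that violate birth < death, are dropped with a message giving the
#' count (genealogical sources contain incomplete dates; no imputation is
#' attempted).
#'
#' @param path file path.
#' @param birth_col,death_col,sex_col column names in the file.
#' @param sex_map named character vector mapping file codes to
#'   `"male"`/`"female"`. The default accepts M/F, man/kvinna and 1/2.
#' @return tibble with columns `birth_date`, `death_date` (`Date`) and `sex`
#'   (`"male"`/`"female"`).
#' @export
read_person_records <- function(path,
                                birth_col = "birth_date",
                                death_col = "death_date",
                                sex_col = "sex",
                                sex_map = default_sex_map()) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  for (col in c(birth_col, death_col, sex_col)) {
    if (!col %in% names(raw)) stop("column `", col, "` not found in ", path)
  }
  out <- tibble::tibble(
    birth_date = parse_flex_date(raw[[birth_col]]),
    death_date = parse_flex_date(raw[[death_col]]),
    sex = decode_sex(raw[[sex_col]], sex_map)
  )
  bad <- is.na(out$birth_date) | is.na(out$death_date) |
    out$death_date <= out$birth_date
  if (any(bad)) {
    message(sum(bad), " record(s) dropped (unparseable dates or death not after birth)")
    out <- out[!bad, ]
  }
  out
}

default_sex_map <- function() {
  c(M = "male", F = "female", m = "male", f = "female",
    man = "male", kvinna = "female", `1` = "male", `2` = "female",
    male = "male", female = "female")
}

parse_flex_date <- function(x) {
  x <- trimws(x)
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  compact <- grepl("^\\d{8}$", x)
  out <- rep(as.Date(NA), length(x))
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out[compact] <- as.Date(x[compact], format = "%Y%m%d")
  out
}

decode_sex <- function(x, sex_map) {
  out <- unname(sex_map[trimws(x)])
  unknown <- !is.na(x) & is.na(out)
  if (any(unknown)) {
    stop("unknown sex code(s): ", paste(unique(x[unknown]), collapse = ", "))
  }
  out
}

#' Form a sex-specific annual birth cohort
#'
#' Selects the records of the given sex born in `birth_year` that survived
#' until the beginning of the year in which they would have turned
#' `start_age` (default 60), i.e. until January 1 of `birth_year + 60` — the
#' follow-up origin `t0`. Members all reached at least their 59th birthday.
#'
#' @param records tibble as returned by [read_person_records()] or
#'   [generate_study()].
#' @param birth_year integer calendar year.
#' @param sex `"male"` or `"female"`.
#' @param start_age age (whole years) whose calendar year opens follow-up.
#' @return a `cohort`: a tibble of the selected members with attributes
#'   `birth_year`, `sex`, `t0` (Date) and `b` (each member's birth day of
#'   year). Empty cohorts are returned (with a message), not errors.
#' @export
build_cohort <- function(records, birth_year, sex, start_age = 60) {
  if (!sex %in% c("male", "female")) stop("`sex` must be \"male\" or \"female\"")
  t0 <- as.Date(sprintf("%d-01-01", birth_year + start_age))
  members <- dplyr::filter(
    records,
    .data$sex == !!sex,
    as.integer(format(.data$birth_date, "%Y")) == birth_year,
    .data$death_date >= t0
  )
  if (nrow(members) == 0L) message("empty cohort: ", birth_year, " ", sex)
  structure(
    tibble::as_tibble(members),
    birth_year = birth_year,
    sex = sex,
    t0 = t0,
    b = day_of_year(members$birth_date),
    class = c("cohort", class(tibble::tibble()))
  )
}

#' Daily risk-set and death-count series for a cohort
#'
#' Puts a cohort on the follow-up clock: day `t = 0` is January 1 of the year
#' members would have turned 60 (`t0`), and the grid runs through December 31
#' of the year they would have turned `end_age_year`. `N[t]` is the number
#' alive at the beginning of day `t`; a person dying on day `t` is counted in
#' `d[t]` and still included in `N[t]`. Deaths after the grid end are
#' right-censored: those persons stay in the risk set for every grid day.
#'
#' @param cohort a `cohort` from [build_cohort()].
#' @param end_age_year last age year of follow-up (default 95).
#' @return tibble with columns `t` (0-based day index), `date`, `N`, `d`, and
#'   attributes `birth_year`, `sex`, `b_mean` (mean birth day of year), `n0`,
#'   `n_censored`.
#' @export
build_daily_counts <- function(cohort, end_age_year = 95) {
  if (nrow(cohort) == 0L) stop("cannot build daily counts for an empty cohort")
  t0 <- attr(cohort, "t0")
  birth_year <- attr(cohort, "birth_year")
  grid_end <- as.Date(sprintf("%d-12-31", birth_year + end_age_year))
  n_days <- as.integer(grid_end - t0) + 1L
  td <- as.integer(cohort$death_date - t0)     # death day index, 0-based
  censored <- td >= n_days
  d <- tabulate(td[!censored] + 1L, nbins = n_days)
  n0 <- nrow(cohort)
  N <- n0 - c(0L, cumsum(d)[-n_days])
  out <- tibble::tibble(
    t = 0:(n_days - 1L),
    date = t0 + 0:(n_days - 1L),
    N = N,
    d = d
  )
  structure(out,
            birth_year = birth_year,
            sex = attr(cohort, "sex"),
            b_mean = mean(attr(cohort, "b")),
            b = attr(cohort, "b"),
            n0 = n0,
            n_censored = sum(censored),
            class = c("daily_counts", class(out)))
}

#' Observed mean lifespan of an extinct cohort
#'
#' The cohorts studied are extinct (every member has a death date), so life
#' expectancy conditional on cohort membership is simply the average lifespan
#' over members: exact day counts divided by 365.25.
#'
#' @param cohort a `cohort` from [build_cohort()].
#' @return mean age at death in years.
#' @export
observed_mean_lifespan <- function(cohort) {
  if (nrow(cohort) == 0L) stop("mean lifespan of an empty cohort is undefined")
  mean(as.numeric(cohort$death_date - cohort$birth_date)) / 365.25
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s %d, %d members, t0 = %s\n",
              attr(x, "sex"), attr(x, "birth_year"), nrow(x),
              format(attr(x, "t0"))))
  NextMethod()
}
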