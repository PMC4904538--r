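#' Describe a mesothelioma case for apportionment
#'
#' Collects the case-level parameters of the risk model: the diagnosis
#' year, the latency lag, the exponent of the time term, an optional
#' plateau cap, and the rounding convention for entry risks.
#'
#' The model weights each exposure by the elapsed time from the exposure
#' year to diagnosis, lagged by `lag_years` (the initial latency period
#' carrying essentially no mesothelioma risk) and raised to
#' `time_exponent`.  The defaults — lag 10 years, exponent 2 — encode
#' the standard epidemiological approximation that mesothelioma rates
#' grow as lagged time since first exposure squared, so an identical
#' exposure twice as far in the past carries a fourfold risk.  An
#' unlagged cubic form (`lag_years = 0`, `time_exponent = 3`) is a
#' recognized alternative that behaves very similarly.
#'
#' `max_years`, when given, is a plateau on time since exposure: cohort
#' evidence suggests pleural mesothelioma rates stop rising roughly
#' 40-45 years after exposure, so the lagged time term saturates at
#' `max_years - lag_years` and grows no further for older exposures.
#' The cap is applied per entry.
#'
#' `rounding = "truncate"` floors each entry's risk to an integer before
#' summation and percentage normalization, matching the printout
#' convention of the original apportionment program; `"exact"` (the
#' default) keeps full floating precision.
#'
#' @param diagnosis_year Calendar year the mesothelioma was diagnosed.
#' @param lag_years Latency lag in years (integer >= 0, default 10).
#' @param time_exponent Power applied to the lagged elapsed time
#'   (> 0, default 2).
#' @param max_years Optional plateau cap in years of time since
#'   exposure (integer > `lag_years`), or `NULL` for no cap.
#' @param rounding `"exact"` or `"truncate"`; see Details.
#' @return An object of class `"case_config"`.
#' @examples
#' case_config(2013)
#' case_config(2013, max_years = 40, rounding = "truncate")
#' @export
case_config <- function(diagnosis_year, lag_years = 10, time_exponent = 2,
                        max_years = NULL,
                        rounding = c("exact", "truncate")) {
  rounding <- match.arg(rounding)
  if (!is_count(diagnosis_year) || diagnosis_year <= 0) {
    stop_input("diagnosis_year must be a positive integer calendar year")
  }
  if (!is_count(lag_years) || lag_years < 0) {
    stop_input("lag_years must be a nonnegative integer")
  }
  if (!is.numeric(time_exponent) || length(time_exponent) != 1 ||
      is.na(time_exponent) || time_exponent <= 0) {
    stop_input("time_exponent must be a single positive number")
  }
  if (!is.null(max_years)) {
    if (!is_count(max_years) || max_years <= lag_years) {
      stop_input("max_years must be an integer greater than lag_years (%d)",
                 lag_years)
    }
    max_years <- as.integer(max_years)
  }
  structure(
    list(
      diagnosis_year = as.integer(diagnosis_year),
      lag_years = as.integer(lag_years),
      time_exponent = as.numeric(time_exponent),
      max_years = max_years,
      rounding = rounding
    ),
    class = "case_config"
  )
}

#' @export
print.case_config <- function(x, ...) {
  cat(sprintf("Mesothelioma case: diagnosis year %d\n", x$diagnosis_year))
  cat(sprintf("  time weight: (elapsed years - %d lag)^%g%s\n",
              x$lag_years, x$time_exponent,
              if (is.null(x$max_years)) "" else
                sprintf(", plateau at %d years since exposure", x$max_years)))
  cat(sprintf("  entry-risk rounding: %s\n", x$rounding))
  invisible(x)
}

#' Lagged elapsed time from exposure to diagnosis
#'
#' The effective time term of the risk model for an exposure year:
#' `diagnosis_year - (entry_year + lag_years)`, floored at zero
#' (exposures inside the latency lag contribute no risk), and capped at
#' `max_years - lag_years` when the case has a plateau.
#'
#' @param entry_year Calendar year(s) of exposure; must not exceed the
#'   diagnosis year.
#' @param config A [case_config()].
#' @return Numeric vector of lagged elapsed times in years (>= 0).
#' @examples
#' lagged_time(1965, case_config(2013))  # 38
#' @export
lagged_time <- function(entry_year, config) {
  stopifnot(inherits(config, "case_config"))
  entry_year <- as.numeric(entry_year)
  if (any(is.na(entry_year))) {
    stop_input("entry_year contains missing values")
  }
  if (any(entry_year > config$diagnosis_year)) {
    stop_input("exposure after diagnosis: entry year %d is later than %d",
               max(entry_year), config$diagnosis_year)
  }
  t <- pmax(config$diagnosis_year - (entry_year + config$lag_years), 0)
  if (!is.null(config$max_years)) {
    t <- pmin(t, config$max_years - config$lag_years)
  }
  t
}

#' Absolute mesotheliogenic risk of each exposure entry
#'
#' The model's contribution score for each row of an exposure history:
#' `concentration * potency * months/12 * lagged_time^time_exponent`.
#' Risk is linear in dose — concentration, potency and months each scale
#' it proportionally — and the time weight is [lagged_time()] raised to
#' the configured exponent.  Under `rounding = "truncate"` each risk is
#' additionally floored to an integer.
#'
#' Entries falling inside the latency lag (lagged time 0) are legal but
#' contribute zero risk; a warning flags them.
#'
#' @param entries An exposure history (see [exposure_history()], or any
#'   data frame passing [validate_exposures()]).
#' @param config A [case_config()].
#' @return Numeric vector of nonnegative risks, one per row of
#'   `entries`.
#' @examples
#' h <- exposure_history(1965, 4, 1, 6)
#' entry_risk(h, case_config(2013, rounding = "truncate"))  # 2888
#' @export
entry_risk <- function(entries, config) {
  stopifnot(inherits(config, "case_config"))
  entries <- validate_exposures(entries)
  t <- lagged_time(entries$year, config)
  if (any(t == 0)) {
    warning(sprintf(
      "%d entr%s within the %d-year latency lag contribute zero risk (year%s %s)",
      sum(t == 0), if (sum(t == 0) == 1) "y lies" else "ies lie",
      config$lag_years, if (sum(t == 0) == 1) "" else "s",
      paste(entries$year[t == 0], collapse = ", ")),
      call. = FALSE)
  }
  # multiply before dividing by 12 so integer-valued risks stay exact
  risk <- entries$concentration * entries$potency * entries$months *
    t^config$time_exponent / 12
  if (config$rounding == "truncate") risk <- floor_guard(risk)
  risk
}
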