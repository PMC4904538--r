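#' Build an exposure history
#'
#' Constructs a validated table of above-background asbestos exposure
#' periods, one row per (year, months) period.  Arguments are recycled
#' to a common length, so a whole history can be built in one call.
#'
#' Concentrations are relative average 8-hour time-weighted-average
#' exposure levels; only their ratios matter for apportionment, so the
#' lowest exposure can be assigned 1 and the rest entered as multiples.
#' Alternatively a cumulative dose in fiber/cc-years can be entered in
#' the `concentration` field with `months = 12` for that year.  Potency
#' is the fiber type's relative mesotheliogenic potency (commercial
#' chrysotile = 1 by convention; see [preset_potency()]).
#'
#' The same (year, months) period may appear in several rows, e.g. for
#' concurrent exposure to more than one product; each row contributes
#' independently.
#'
#' @param year Calendar year of exposure (positive integer).
#' @param months Months of exposure within that year; real in (0, 12],
#'   fractional values allowed.
#' @param concentration Relative 8-hour TWA concentration (> 0), or a
#'   dose in fiber/cc-years entered with `months = 12`.
#' @param potency Relative mesotheliogenic potency of the fiber (> 0).
#' @param description Optional free-text label, e.g. a plant name.
#' @param group Optional free-text group label, e.g. a product name;
#'   rows sharing a group are subtotaled together by [apportion()].
#' @return A data frame of class `"exposure_history"` with columns
#'   `year`, `months`, `concentration`, `potency`, `description`,
#'   `group`.
#' @seealso [expand_range()] to repeat one period over a span of years,
#'   [read_exposures()] for CSV input, [apportion()].
#' @examples
#' exposure_history(
#'   year = c(1965, 1966), months = c(4, 2),
#'   concentration = 1, potency = 6,
#'   description = "Plant A", group = "Product A"
#' )
#' @export
exposure_history <- function(year, months, concentration, potency,
                             description = "", group = "") {
  n <- max(length(year), length(months), length(concentration),
           length(potency), length(description), length(group))
  entries <- data.frame(
    year          = rep_len(as.numeric(year), n),
    months        = rep_len(as.numeric(months), n),
    concentration = rep_len(as.numeric(concentration), n),
    potency       = rep_len(as.numeric(potency), n),
    description   = rep_len(as.character(description), n),
    group         = rep_len(as.character(group), n),
    stringsAsFactors = FALSE
  )
  validate_exposures(entries)
}

#' Validate an exposure history
#'
#' Checks the row-level invariants of an exposure table: `year` a
#' positive integer, `0 < months <= 12`, `concentration > 0` and
#' `potency > 0` (entries represent above-background exposure only, so
#' a zero is treated as a data-entry mistake rather than a measurement).
#' Errors name the offending row and field.
#'
#' @param entries A data frame with columns `year`, `months`,
#'   `concentration`, `potency` and optionally `description`, `group`.
#' @return The validated table, classed `"exposure_history"`, with
#'   missing label columns filled with `""`.
#' @export
validate_exposures <- function(entries) {
  if (!is.data.frame(entries)) {
    stop_input("exposure history must be a data frame")
  }
  required <- c("year", "months", "concentration", "potency")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0) {
    stop_input("exposure history is missing column(s): %s",
               paste(missing, collapse = ", "))
  }
  if (nrow(entries) == 0) {
    stop_input("exposure history has no rows")
  }
  for (lab in c("description", "group")) {
    if (is.null(entries[[lab]])) entries[[lab]] <- ""
    entries[[lab]] <- as.character(entries[[lab]])
    entries[[lab]][is.na(entries[[lab]])] <- ""
  }
  for (col in required) {
    entries[[col]] <- as.numeric(entries[[col]])
  }

  check <- function(bad, field, rule) {
    if (any(bad)) {
      stop_input("invalid %s in row %d: %s", field, which(bad)[1], rule)
    }
  }
  check(is.na(entries$year) | entries$year <= 0 |
          entries$year != trunc(entries$year),
        "year", "must be a positive integer calendar year")
  check(is.na(entries$months) | entries$months <= 0 | entries$months > 12,
        "months", "must satisfy 0 < months <= 12")
  check(is.na(entries$concentration) | entries$concentration <= 0,
        "concentration",
        "must be > 0 (above-background exposures only)")
  check(is.na(entries$potency) | entries$potency <= 0,
        "potency", "must be > 0 (above-background exposures only)")

  rownames(entries) <- NULL
  class(entries) <- unique(c("exposure_history", class(entries)))
  entries
}

#' Expand one exposure period over a range of years
#'
#' Repeats a single (months, concentration, potency) exposure pattern
#' for every calendar year from `start_year` to `end_year` inclusive,
#' for histories such as "similar work, similar exposure, 1966 to 1970".
#'
#' @param start_year,end_year First and last calendar year of the span
#'   (inclusive); `start_year <= end_year`.
#' @inheritParams exposure_history
#' @return An `"exposure_history"` with one row per year, ordered by
#'   year.
#' @examples
#' expand_range(1966, 1970, months = 12, concentration = 1, potency = 1,
#'              group = "misc. products")
#' @export
expand_range <- function(start_year, end_year, months, concentration,
                         potency, description = "", group = "") {
  if (!is_count(start_year) || !is_count(end_year)) {
    stop_input("start_year and end_year must be single integer years")
  }
  if (start_year > end_year) {
    stop_input("invalid year range: start_year (%d) exceeds end_year (%d)",
               start_year, end_year)
  }
  exposure_history(
    year = seq.int(start_year, end_year),
    months = months, concentration = concentration, potency = potency,
    description = description, group = group
  )
}
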