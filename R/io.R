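# CSV input/output and report rendering.
#
# File dialect: UTF-8, comma delimiter, "." decimal separator, header
# row required.  Columns: year, months, concentration, potency and
# optionally description, group, end_year; a nonempty end_year expands
# the row into one entry per year through end_year (see expand_range).

#' Read an exposure history from a CSV file
#'
#' Parses a comma-separated exposure table with a header row and columns
#' `year`, `months`, `concentration`, `potency` plus optional
#' `description`, `group` and `end_year`.  Rows carrying a nonempty
#' `end_year` are expanded into one entry per calendar year from `year`
#' to `end_year` via [expand_range()].  Label whitespace is trimmed;
#' parse and invariant errors name the offending row and column.
#'
#' @param path Path to a UTF-8 CSV file (or a connection).
#' @return An `"exposure_history"` data frame in file order (expanded
#'   rows in year order).
#' @seealso [write_exposures()], [example_exposures()]
#' @export
read_exposures <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, fileEncoding = "UTF-8")
  required <- c("year", "months", "concentration", "potency")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_input("exposure file is missing required column(s): %s",
               paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) stop_input("exposure file has no data rows")
  for (lab in c("description", "group")) {
    if (is.null(raw[[lab]])) raw[[lab]] <- ""
  }
  if (is.null(raw$end_year)) raw$end_year <- ""

  num_cell <- function(cell, row, col, allow_blank = FALSE) {
    if (is.na(cell) || cell == "") {
      if (allow_blank) return(NA_real_)
      stop_input("row %d, column '%s': value is missing", row, col)
    }
    v <- suppressWarnings(as.numeric(cell))
    if (is.na(v)) {
      stop_input("row %d, column '%s': cannot parse '%s' as a number",
                 row, col, cell)
    }
    v
  }

  parts <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    year <- num_cell(raw$year[i], i, "year")
    end_year <- num_cell(raw$end_year[i], i, "end_year", allow_blank = TRUE)
    args <- list(
      months = num_cell(raw$months[i], i, "months"),
      concentration = num_cell(raw$concentration[i], i, "concentration"),
      potency = num_cell(raw$potency[i], i, "potency"),
      description = trimws(raw$description[i]),
      group = trimws(raw$group[i])
    )
    parts[[i]] <- tryCatch(
      {
        if (is.na(end_year)) {
          do.call(exposure_history, c(list(year = year), args))
        } else {
          if (end_year < year) {
            stop_input("end_year (%g) is before year (%g)", end_year, year)
          }
          do.call(expand_range,
                  c(list(start_year = year, end_year = end_year), args))
        }
      },
      error = function(e) {
        stop_input("row %d: %s", i, conditionMessage(e))
      }
    )
  }
  validate_exposures(do.call(rbind, parts))
}

#' Write an exposure history to CSV
#'
#' Writes the six exposure columns at full floating precision, so that
#' [read_exposures()] reproduces the history exactly.
#'
#' @param entries An exposure history.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exposures <- function(entries, path) {
  entries <- validate_exposures(entries)
  out <- data.frame(
    year = sprintf("%d", as.integer(entries$year)),
    months = sprintf("%.17g", entries$months),
    concentration = sprintf("%.17g", entries$concentration),
    potency = sprintf("%.17g", entries$potency),
    description = entries$description,
    group = entries$group,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The bundled worked example history
#'
#' The eight-entry exposure history used throughout the documentation:
#' a hypothetical mesothelioma diagnosed in 2013, with work on a
#' mixed-fiber "product A" (potency 6) at Plant A in 1965 (4 months) and
#' 1966 (2 months) plus a brief half-month re-exposure in 1969, and
#' chrysotile-only work around miscellaneous asbestos-containing
#' materials (potency 1) from 1966 to 1970.  Run it with
#' `apportion(example_exposures(), case_config(2013, rounding =
#' "truncate"))`.
#'
#' @return An `"exposure_history"` of 8 entries.
#' @export
example_exposures <- function() {
  read_exposures(system.file("extdata", "example_exposures.csv",
                             package = "mesoapportion", mustWork = TRUE))
}

format_risk <- function(risk, rounding) {
  if (rounding == "truncate") {
    format(risk, scientific = FALSE, trim = TRUE)
  } else {
    sprintf("%.2f", round_half_up(risk))
  }
}

format_percent <- function(percent) {
  sprintf("%.2f%%", round_half_up(percent))
}

#' Render an apportionment report
#'
#' Renders the result of [apportion()] as a printable text table (the
#' layout of the original program's printout: per-group member rows,
#' subtotal lines, grand total), as CSV, or as JSON.  Text and the
#' `*_display` CSV/JSON fields use display rounding — percents half-up
#' to two decimals, risks as integers in `truncate` mode — while the
#' CSV/JSON `risk` and `percent` fields keep full precision.  Displayed
#' percents are not force-balanced, so they may sum to a cent or two
#' off 100.
#'
#' @param report An `"apportionment"` object.
#' @param format `"text"`, `"csv"` or `"json"`.
#' @param file Optional path; when given the document is also written
#'   there.
#' @return The rendered document as a single character string
#'   (invisibly when `file` is given).
#' @export
render_report <- function(report, format = c("text", "csv", "json"),
                          file = NULL) {
  stopifnot(inherits(report, "apportionment"))
  format <- match.arg(format)
  doc <- switch(format,
                text = render_text(report),
                csv = render_csv(report),
                json = render_json(report))
  if (!is.null(file)) {
    writeLines(doc, file, sep = "")
    return(invisible(doc))
  }
  doc
}

render_text <- function(report) {
  e <- report$entries
  g <- report$groups
  rounding <- report$config$rounding
  row_fmt <- "%-6s%-8s%-15s%-9s%-16s%-18s%10s%10s\n"
  lines <- character(0)
  add <- function(...) lines[[length(lines) + 1]] <<- sprintf(...)

  add("Mesothelioma year diagnosis: %d\n\n", report$config$diagnosis_year)
  add(row_fmt, "Year", "Months", "Concentration", "Potency",
      "Description", "Group description", "Result", "Percent")
  for (k in seq_len(nrow(g))) {
    add("Group description: %s\n", g$group[k])
    m <- e[e$group == g$group[k], , drop = FALSE]
    for (j in seq_len(nrow(m))) {
      add(row_fmt, m$year[j],
          format(m$months[j], trim = TRUE),
          format(m$concentration[j], trim = TRUE),
          format(m$potency[j], trim = TRUE),
          m$description[j], m$group[j],
          format_risk(m$risk[j], rounding),
          format_percent(m$percent[j]))
    }
    add(row_fmt, "", "", "", "", "", "Subtotal",
        format_risk(g$subtotal_risk[k], rounding),
        format_percent(g$subtotal_percent[k]))
    add("\n")
  }
  add(row_fmt, "", "", "", "", "", "Total",
      format_risk(report$total_risk, rounding), "100.00%")
  paste(lines, collapse = "")
}

render_csv <- function(report) {
  e <- report$entries
  g <- report$groups
  rounding <- report$config$rounding
  entry_rows <- data.frame(
    row_type = "entry",
    group = e$group, year = e$year, months = sprintf("%.17g", e$months),
    concentration = sprintf("%.17g", e$concentration),
    potency = sprintf("%.17g", e$potency),
    description = e$description,
    lagged_time = sprintf("%.17g", e$lagged_time),
    risk = sprintf("%.17g", e$risk),
    percent = sprintf("%.17g", e$percent),
    risk_display = format_risk(e$risk, rounding),
    percent_display = sprintf("%.2f", round_half_up(e$percent)),
    stringsAsFactors = FALSE
  )
  blank <- rep("", nrow(g))
  subtotal_rows <- data.frame(
    row_type = "subtotal", group = g$group, year = blank, months = blank,
    concentration = blank, potency = blank, description = blank,
    lagged_time = blank,
    risk = sprintf("%.17g", g$subtotal_risk),
    percent = sprintf("%.17g", g$subtotal_percent),
    risk_display = format_risk(g$subtotal_risk, rounding),
    percent_display = sprintf("%.2f", round_half_up(g$subtotal_percent)),
    stringsAsFactors = FALSE
  )
  total_row <- data.frame(
    row_type = "total", group = "", year = "", months = "",
    concentration = "", potency = "", description = "", lagged_time = "",
    risk = sprintf("%.17g", report$total_risk), percent = "100",
    risk_display = format_risk(report$total_risk, rounding),
    percent_display = "100.00", stringsAsFactors = FALSE
  )
  con <- textConnection("csvdoc", "w", local = TRUE)
  utils::write.csv(rbind(entry_rows, subtotal_rows, total_row), con,
                   row.names = FALSE)
  close(con)
  paste0(paste(csvdoc, collapse = "\n"), "\n")
}

render_json <- function(report) {
  e <- report$entries
  g <- report$groups
  rounding <- report$config$rounding
  cfg <- report$config
  groups <- lapply(seq_len(nrow(g)), function(k) {
    m <- e[e$group == g$group[k], , drop = FALSE]
    list(
      group = g$group[k],
      subtotal_risk = g$subtotal_risk[k],
      subtotal_percent = g$subtotal_percent[k],
      subtotal_percent_display = round_half_up(g$subtotal_percent[k]),
      entries = lapply(seq_len(nrow(m)), function(j) {
        list(year = m$year[j], months = m$months[j],
             concentration = m$concentration[j], potency = m$potency[j],
             description = m$description[j], group = m$group[j],
             lagged_time = m$lagged_time[j], risk = m$risk[j],
             percent = m$percent[j],
             percent_display = round_half_up(m$percent[j]))
      })
    )
  })
  doc <- list(
    config = list(diagnosis_year = cfg$diagnosis_year,
                  lag_years = cfg$lag_years,
                  time_exponent = cfg$time_exponent,
                  max_years = cfg$max_years,
                  rounding = rounding),
    groups = groups,
    total_risk = report$total_risk
  )
  # digits = I(17): 17 significant digits round-trip doubles exactly
  paste0(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                          null = "null", pretty = TRUE), "\n")
}
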