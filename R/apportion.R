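#' Apportion mesothelioma risk across an exposure history
#'
#' The central computation: evaluates each entry's absolute
#' mesotheliogenic risk via [entry_risk()], normalizes risks to
#' percentage contributions (`risk_i / sum(risk) * 100`), and groups and
#' subtotals entries by their group label.  Because the percentages are
#' ratios, only relative concentrations and potencies matter — any
#' common scaling of a factor cancels out.
#'
#' Under `rounding = "truncate"` in the case configuration, entry risks
#' are floored to integers before both subtotaling and normalization,
#' so percentages are ratios of truncated integers, as in the original
#' program's printout.
#'
#' Report order: groups appear in order of first appearance in the
#' input (`group_order = "input"`) or alphabetically
#' (`group_order = "label"`); entries within a group are ordered by
#' year, then input order.  Blank group labels are collected under
#' `"(ungrouped)"`; labels are matched exactly after trimming
#' surrounding whitespace.
#'
#' @param entries An exposure history (see [exposure_history()],
#'   [read_exposures()]).
#' @param config A [case_config()].
#' @param group_order `"input"` (first appearance; default) or
#'   `"label"` (alphabetical) ordering of groups in the report.
#' @return An object of class `"apportionment"`: a list with components
#'   \describe{
#'     \item{config}{the case configuration}
#'     \item{entries}{data frame in report order with the input columns
#'       plus `lagged_time`, `risk` and `percent`}
#'     \item{groups}{data frame of `group`, `n_entries`,
#'       `subtotal_risk`, `subtotal_percent`}
#'     \item{total_risk}{sum of all entry risks}
#'   }
#'   with `print()`, `summary()`, `as.data.frame()` and
#'   [render_report()] methods.
#' @examples
#' h <- rbind(
#'   expand_range(1966, 1970, 12, 1, 1, group = "misc. products"),
#'   exposure_history(1965, 4, 1, 6, "Plant A", "Product A")
#' )
#' apportion(h, case_config(2013))
#' @export
apportion <- function(entries, config, group_order = c("input", "label")) {
  stopifnot(inherits(config, "case_config"))
  group_order <- match.arg(group_order)
  if (is.data.frame(entries) && nrow(entries) == 0) {
    stop_input("nothing to apportion: exposure history is empty")
  }
  entries <- validate_exposures(entries)

  risk <- entry_risk(entries, config)
  total <- sum(risk)
  if (total <= 0) {
    stop_input(paste0(
      "no entry contributes risk (all exposures fall within the ",
      "latency lag); cannot apportion"))
  }

  tab <- entries
  tab$group <- normalize_group(tab$group)
  tab$lagged_time <- lagged_time(tab$year, config)
  tab$risk <- risk
  tab$percent <- risk / total * 100

  glabels <- unique(tab$group)
  if (group_order == "label") glabels <- sort(glabels)
  gindex <- match(tab$group, glabels)
  ord <- order(gindex, tab$year, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL

  groups <- data.frame(
    group = glabels,
    n_entries = as.integer(tapply(rep(1, nrow(tab)), factor(tab$group, glabels), sum)),
    subtotal_risk = as.numeric(tapply(tab$risk, factor(tab$group, glabels), sum)),
    subtotal_percent = as.numeric(tapply(tab$percent, factor(tab$group, glabels), sum)),
    stringsAsFactors = FALSE
  )
  rownames(groups) <- NULL

  structure(
    list(config = config, entries = tab, groups = groups,
         total_risk = total),
    class = "apportionment"
  )
}

#' @export
print.apportionment <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "")
  invisible(x)
}

#' @rdname apportion
#' @param object,x An `"apportionment"` object.
#' @param ... Unused.
#' @export
summary.apportionment <- function(object, ...) {
  out <- list(
    diagnosis_year = object$config$diagnosis_year,
    rounding = object$config$rounding,
    n_entries = nrow(object$entries),
    groups = object$groups,
    total_risk = object$total_risk
  )
  class(out) <- "summary.apportionment"
  out
}

#' @export
print.summary.apportionment <- function(x, ...) {
  cat(sprintf("Apportionment of mesothelioma risk (diagnosis %d, %s mode)\n",
              x$diagnosis_year, x$rounding))
  cat(sprintf("  %d exposure entries in %d group(s); total risk %s\n\n",
              x$n_entries, nrow(x$groups), format_risk(x$total_risk, x$rounding)))
  g <- x$groups
  g$subtotal_risk <- format_risk(g$subtotal_risk, x$rounding)
  g$subtotal_percent <- sprintf("%.2f%%", round_half_up(g$subtotal_percent))
  print.data.frame(g, row.names = FALSE)
  invisible(x)
}

#' @rdname apportion
#' @export
as.data.frame.apportionment <- function(x, ...) {
  as.data.frame(x$entries, ...)
}

#' Re-apportion under alternative group potency multipliers
#'
#' Runs [apportion()] once per override set, with the potencies of named
#' groups multiplied by the given factors.  Useful for sensitivity
#' analysis of the amphibole:chrysotile potency ratio: since only
#' relative potencies enter the percentages, rescaling one group's
#' potency shows directly how the apportionment depends on that ratio.
#'
#' @param entries An exposure history.
#' @param config A [case_config()].
#' @param potency_overrides A named numeric vector (one override set) or
#'   a list of named numeric vectors (several sets); names are group
#'   labels, values are positive multipliers applied to those groups'
#'   potencies.
#' @return A named list of `"apportionment"` objects, one per override
#'   set.  Input entries are not modified.
#' @examples
#' h <- rbind(
#'   expand_range(1966, 1970, 12, 1, 1, group = "misc. products"),
#'   exposure_history(1965, 4, 1, 6, group = "Product A")
#' )
#' sensitivity_over_potency(h, case_config(2013),
#'                          list(amphibole = c("Product A" = 50 / 6)))
#' @export
sensitivity_over_potency <- function(entries, config, potency_overrides) {
  entries <- validate_exposures(entries)
  if (is.numeric(potency_overrides)) {
    potency_overrides <- list(potency_overrides)
  }
  if (!is.list(potency_overrides) || length(potency_overrides) == 0) {
    stop_input("potency_overrides must be a named numeric vector or a list of them")
  }
  if (is.null(names(potency_overrides)) || any(names(potency_overrides) == "")) {
    names(potency_overrides) <- paste0("set", seq_along(potency_overrides))
  }
  groups <- normalize_group(entries$group)
  lapply(potency_overrides, function(ov) {
    if (!is.numeric(ov) || is.null(names(ov)) || any(names(ov) == "")) {
      stop_input("each override set must be a named numeric vector of multipliers")
    }
    if (any(ov <= 0 | is.na(ov))) {
      stop_input("potency multipliers must be positive")
    }
    unknown <- setdiff(trimws(names(ov)), groups)
    if (length(unknown) > 0) {
      stop_input("unknown group label(s) in overrides: %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(unique(groups), collapse = ", "))
    }
    mod <- entries
    mult <- ov[match(groups, trimws(names(ov)))]
    mult[is.na(mult)] <- 1
    mod$potency <- mod$potency * as.numeric(mult)
    apportion(mod, config)
  })
}
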