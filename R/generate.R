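#' Generate a random exposure history
#'
#' Deterministic (per seed) generator of valid exposure histories, for
#' simulation studies and property testing of the apportionment
#' pipeline.  Exposure years are drawn uniformly from `year_range`,
#' months uniformly from [0.5, 12], concentrations log-uniformly from
#' [0.2, 10] (relative TWA levels spanning about two orders of
#' magnitude), and potencies from the preset fiber-type constants
#' (1, 6, 35, 50, 100, 200, 500) weighted toward the common low-potency
#' chrysotile exposures.  Group labels are assigned from `n_groups`
#' generic names.
#'
#' The caller's random-number-generator state is preserved.
#'
#' @param seed Integer seed; identical seeds give identical histories.
#' @param n_entries Number of entries to generate (>= 1).
#' @param year_range Length-2 integer vector `c(first, last)` of
#'   permissible exposure years, with `first <= last < diagnosis_year`.
#' @param diagnosis_year Calendar year of diagnosis (bounds the years).
#' @param n_groups Number of distinct group labels to draw from
#'   (default 3).
#' @return An `"exposure_history"` of `n_entries` rows ordered by year.
#' @examples
#' h <- generate_history(1, 10, c(1950, 1990), 2013)
#' apportion(h, case_config(2013))
#' @export
generate_history <- function(seed, n_entries, year_range, diagnosis_year,
                             n_groups = 3) {
  if (!is_count(seed)) stop_input("seed must be a single integer")
  if (!is_count(n_entries) || n_entries < 1) {
    stop_input("n_entries must be a positive integer")
  }
  if (length(year_range) != 2 || !is_count(year_range[1]) ||
      !is_count(year_range[2]) || year_range[1] > year_range[2]) {
    stop_input("year_range must be c(first, last) with first <= last")
  }
  if (!is_count(diagnosis_year) || year_range[2] >= diagnosis_year) {
    stop_input("year_range must end before diagnosis_year")
  }
  if (!is_count(n_groups) || n_groups < 1) {
    stop_input("n_groups must be a positive integer")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  potency_pool <- c(1, 6, 35, 50, 100, 200, 500)
  potency_wts <- c(0.40, 0.20, 0.10, 0.10, 0.08, 0.07, 0.05)
  labels <- sprintf("group %s", LETTERS[((seq_len(n_groups) - 1) %% 26) + 1])

  exposure_history(
    year = sort(sample(seq.int(year_range[1], year_range[2]), n_entries,
                       replace = TRUE)),
    months = round(stats::runif(n_entries, 0.5, 12), 1),
    concentration = round(exp(stats::runif(n_entries, log(0.2), log(10))), 3),
    potency = sample(potency_pool, n_entries, replace = TRUE,
                     prob = potency_wts),
    description = "",
    group = sample(labels, n_entries, replace = TRUE)
  )
}
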