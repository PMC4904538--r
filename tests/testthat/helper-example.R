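# Shared fixtures and independent oracles.

# The eight-entry worked example: diagnosis 2013, mixed-fiber product A
# (potency 6) in 1965/1966/1969 plus chrysotile-only miscellaneous work
# (potency 1) 1966-1970.  Built in code, independently of the CSV
# shipped in inst/extdata.
example_history <- function() {
  validate_exposures(rbind(
    exposure_history(
      year = c(1966, 1967, 1968, 1969, 1970),
      months = c(10, 12, 12, 11.5, 12),
      concentration = 1, potency = 1, group = "misc. products"
    ),
    exposure_history(
      year = c(1965, 1966, 1969), months = c(4, 2, 0.5),
      concentration = 1, potency = 6,
      description = c("Plant A", "Plant A", ""), group = "product A"
    )
  ))
}

example_config <- function(rounding = "truncate") {
  case_config(2013, lag_years = 10, time_exponent = 2, rounding = rounding)
}

# Brute-force oracle: recomputes every risk and the normalization from
# scratch with scalar arithmetic, no package internals.
oracle_apportion <- function(entries, diagnosis_year, lag = 10, expo = 2,
                             truncate = FALSE) {
  risk <- numeric(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    t <- diagnosis_year - (entries$year[i] + lag)
    if (t < 0) t <- 0
    r <- entries$concentration[i] * entries$potency[i] *
      (entries$months[i] / 12) * t^expo
    risk[i] <- if (truncate) floor(r + 1e-9) else r
  }
  list(risk = risk, percent = risk / sum(risk) * 100)
}

# Table of the published printout's cells for the worked example, keyed
# by (year, months) which uniquely identifies each row.
example_expected <- data.frame(
  year = c(1966, 1967, 1968, 1969, 1970, 1965, 1966, 1969),
  months = c(10, 12, 12, 11.5, 12, 4, 2, 0.5),
  result = c(1140, 1296, 1225, 1107, 1089, 2888, 1369, 289),
  percent = c(10.96, 12.46, 11.78, 10.64, 10.47, 27.76, 13.16, 2.78)
)
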