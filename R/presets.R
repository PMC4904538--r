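# Literature-derived relative mesotheliogenic potency constants,
# commercial chrysotile = 1.  "lifetime" and "occupational" are the
# Hodgson-Darnton exposure-scenario ratios (1:100:500 lifetime,
# 1:35:200 occupational for chrysotile:amosite:crocidolite);
# "example" is the illustrative 50:1 generic amphibole:chrysotile
# choice an operator might adopt when fiber speciation is unknown.
.potency_presets <- data.frame(
  fiber_type = c("commercial_chrysotile", "commercial_chrysotile",
                 "commercial_chrysotile", "amosite", "amosite",
                 "crocidolite", "crocidolite", "generic_amphibole"),
  scenario = c("lifetime", "occupational", "example",
               "lifetime", "occupational",
               "lifetime", "occupational", "example"),
  relative_potency = c(1, 1, 1, 100, 35, 500, 200, 50),
  stringsAsFactors = FALSE
)

#' Relative potency presets for asbestos fiber types
#'
#' Tabulated relative mesotheliogenic potencies (commercial chrysotile
#' = 1) from the fiber-type epidemiology literature, for populating the
#' `potency` field of an exposure history.  Two scenarios carry the
#' published chrysotile:amosite:crocidolite ratios — `"lifetime"`
#' (1:100:500) and `"occupational"` (1:35:200) — and the `"example"`
#' scenario holds an illustrative generic amphibole:chrysotile ratio of
#' 50:1.  The presets are advisory: the apportionment engine never
#' substitutes them silently, the operator always supplies the potency
#' values.
#'
#' The same table ships as a machine-readable CSV at
#' `system.file("extdata", "potency_presets.csv",
#' package = "mesoapportion")`.
#'
#' @return `potency_presets()`: the full preset table as a data frame
#'   with columns `fiber_type`, `scenario`, `relative_potency`.
#' @examples
#' potency_presets()
#' preset_potency("crocidolite", "lifetime")     # 500
#' preset_potency("amosite", "occupational")     # 35
#' @export
potency_presets <- function() {
  .potency_presets
}

#' @rdname potency_presets
#' @param fiber_type One of `"commercial_chrysotile"`, `"amosite"`,
#'   `"crocidolite"`, `"generic_amphibole"`.
#' @param scenario One of `"lifetime"`, `"occupational"`, `"example"`.
#' @return `preset_potency()`: the tabulated relative potency (a single
#'   positive number).
#' @export
preset_potency <- function(fiber_type, scenario) {
  hit <- .potency_presets$fiber_type == fiber_type &
    .potency_presets$scenario == scenario
  if (!any(hit)) {
    valid <- paste(sprintf("(%s, %s)", .potency_presets$fiber_type,
                           .potency_presets$scenario), collapse = ", ")
    stop_input("no preset for fiber_type '%s', scenario '%s'; valid combinations: %s",
               fiber_type, scenario, valid)
  }
  .potency_presets$relative_potency[hit]
}

#' Average potency of a mixed-fiber exposure
#'
#' Weighted mean of component potencies for exposure to a mixture of
#' fiber types, e.g. a workplace where about 90% of asbestos in use was
#' chrysotile (potency 1) and 10% amphibole (potency 50) has average
#' potency `0.9 * 1 + 0.1 * 50 = 5.9`, i.e. about 6.
#'
#' @param fractions Numeric vector of mixture fractions in `[0, 1]`,
#'   summing to 1.
#' @param potencies Positive potencies, one per fraction.
#' @return The mixture's relative potency, `sum(fractions * potencies)`.
#' @examples
#' mixed_potency(c(0.9, 0.1), c(1, 50))  # 5.9
#' @export
mixed_potency <- function(fractions, potencies) {
  if (length(fractions) == 0 || length(fractions) != length(potencies)) {
    stop_input("fractions and potencies must be nonempty vectors of equal length")
  }
  if (any(is.na(fractions)) || any(fractions < 0) || any(fractions > 1)) {
    stop_input("fractions must lie in [0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop_input("fractions must sum to 1 (got %.12g)", sum(fractions))
  }
  if (any(is.na(potencies)) || any(potencies <= 0)) {
    stop_input("potencies must be positive")
  }
  sum(fractions * potencies)
}
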