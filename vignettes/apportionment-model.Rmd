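---
title: "The mesothelioma apportionment model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mesothelioma apportionment model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoapportion)
```

## The problem

Once a mesothelioma has been judged asbestos-related, apportioning it
among the products, workplaces and time periods of an exposure history
is a purely arithmetic — but error-prone — exercise. `mesoapportion`
encodes the standard epidemiological weighting so that the arithmetic
is reproducible and auditable. It deliberately does **not** decide
whether a mesothelioma is asbestos-related, estimate what the actual
exposures or potencies were, or model background (non-asbestos)
mesothelioma risk: the operator supplies the relative exposure and
potency values, and the package apportions among them.

## The model and its assumptions

Each above-background exposure period $i$ contributes an absolute
mesotheliogenic risk

$$\mathrm{risk}_i = c_i \, p_i \, \frac{m_i}{12} \, T_i^{\,e},
\qquad T_i = \max\bigl(0,\; Y - (y_i + L)\bigr),$$

optionally capped at $M - L$, and its percentage contribution is
$\mathrm{risk}_i / \sum_j \mathrm{risk}_j \times 100$. The assumptions
behind each factor:

* **Linearity in dose.** Risk is proportional to the relative 8-hour
  TWA concentration $c_i$, to the fiber potency $p_i$ and to the
  months of exposure $m_i$. Threshold doses and possibly supralinear
  concentration effects are discussed in the epidemiological
  literature, but no above-background exposure can yet be shown to
  contribute nothing, so every entry contributes in proportion to its
  dose. Entries with nonpositive concentration or potency are rejected
  as data-entry mistakes rather than treated as zero-risk rows.
* **Power-law time weighting.** Mesothelioma rates grow roughly as a
  power of time since exposure; the standard approximation is time
  since first exposure, lagged by $L = 10$ years (the initial latency
  period carrying essentially no risk) and squared ($e = 2$). Hence an
  identical exposure twice as far in the past carries exactly a
  fourfold risk. An unlagged cube ($L = 0$, $e = 3$) behaves very
  similarly and can be selected through `case_config()`.
* **Scale invariance.** Only ratios enter the percentages, so the
  operator may anchor the smallest concentration at 1 and express all
  others as multiples, and likewise choose any potency scale with
  commercial chrysotile at 1. Genetic and host factors are assumed to
  multiply all entries equally and therefore cancel.

Exposures inside the latency lag are legal input — they simply score
zero, with a warning rather than an error, since a patient may well
report them.

## Tunable parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `diagnosis_year` | calendar year | — | year the mesothelioma was diagnosed |
| `lag_years` | years | 10 | latency lag subtracted before the power is applied |
| `time_exponent` | — | 2 | power on the lagged elapsed time |
| `max_years` | years | none | plateau: time since exposure beyond which the time weight stops growing |
| `rounding` | — | `"exact"` | `"truncate"` floors each entry risk to an integer before summation |

`max_years` reflects cohort evidence that pleural mesothelioma rates
stop rising roughly 40–45 years after exposure. Two readings of the
cap were possible: anchoring it to the single earliest exposure of the
whole history, or applying it per entry. The per-entry reading was
chosen because the risk formula itself is per-entry, and a history-level
anchor would make one entry's score depend on the presence of another,
breaking the additivity the normalization relies on. Thus each entry's
$T_i$ saturates at $M - L$.

`rounding = "truncate"` exists to reproduce the printout convention of
the original apportionment program, whose reports show integer risk
scores whose subtotals equal sums of the truncated values; truncation is
applied before both subtotaling and normalization, so in that mode the
percentages are ratios of truncated integers. Either floor or
round-half-down reproduces the published example; floor was chosen as
the simpler convention. The default `exact` mode keeps full floating
precision and is preferable for real use.

## Numerical choices

* Risks are computed as $c\,p\,m\,T^e / 12$ — multiplying before the
  single division — so that integer-valued results stay exactly
  representable; truncation adds a `+1e-9` absolute guard so a product
  that is an integer in exact arithmetic is not pushed below it by
  floating error.
* Display percentages are rounded half-up to two decimals (the
  convention of printed reports; base `round()` ties to even), only at
  rendering. Displayed percents may therefore sum to 100 ± 0.02; they
  are **not** force-balanced, because adjusting a cell to make the
  column sum exactly 100 would misreport that cell.
* Group labels are matched case-sensitively after trimming surrounding
  whitespace; blank labels collect in an explicit `"(ungrouped)"`
  bucket. Duplicate (year, months) periods are permitted and contribute
  independently — concurrent exposure to several products in the same
  months is entered as several rows.
* Report order: groups by first appearance in the input (alphabetical
  ordering available via `group_order = "label"`; the original
  printout's layout is consistent with either), entries within a group
  by year then input order.
* Degenerate inputs fail loudly: an empty history, a history whose
  every entry falls inside the lag (total risk 0), exposure years after
  diagnosis, and out-of-range fields all raise errors naming the
  offending row and field.

## The history generator

`generate_history()` produces seed-deterministic random exposure
histories for property testing and simulation: years uniform over the
requested range, months uniform on [0.5, 12], concentrations
log-uniform on [0.2, 10] (relative TWA levels spanning the couple of
orders of magnitude typical of occupational settings), and potencies
drawn from the preset fiber-type constants (1, 6, 35, 50, 100, 200,
500) weighted toward the common low-potency chrysotile exposures.

What it emulates is the *structure* of an exposure history — valid
field ranges, mixed fiber types, multiple groups — not the
epidemiology of real careers: real histories have serially correlated
years and concentrations, and recall error besides. Passing property
tests on generated histories therefore demonstrates the algebraic
invariants of the implementation (conservation of percentages, scale
and permutation invariance, diagnosis-year shift invariance, agreement
with brute-force recomputation), not calibration against real
populations. The test suite exercises these invariants over 200 seeded
histories of up to 50 entries, a size at which the whole suite runs in
seconds; the computation is linear in the number of entries, and real
histories are rarely longer than a few dozen rows.

## Limitations

The model inherits the limitations of its inputs: results are only as
good as the operator's relative concentration and potency estimates,
and memory-based histories carry recall error (though purely
multiplicative errors cancel in the percentages). The model assumes
linearity in dose, ignores possible threshold and concentration-rate
effects, treats fiber potency as a single scalar per entry, and does
not quantify uncertainty on the reported percentages — the report is a
point apportionment. `sensitivity_over_potency()` offers a first-order
check on the assumption that matters most in practice, the
amphibole:chrysotile potency ratio, by re-running the apportionment
under alternative group-potency multipliers.
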