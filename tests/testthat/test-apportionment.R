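test_that("the worked example apportions to the published subtotals and percentages", {
  rep <- apportion(example_history(), example_config("truncate"))

  key <- paste(rep$entries$year, rep$entries$months)
  exp_key <- paste(example_expected$year, example_expected$months)
  idx <- match(key, exp_key)
  expect_false(anyNA(idx))
  expect_identical(rep$entries$risk, example_expected$result[idx])
  expect_equal(round(floor(rep$entries$percent * 100 + 0.5) / 100, 2),
               example_expected$percent[idx], tolerance = 0)

  g <- rep$groups[order(rep$groups$group), ]
  expect_identical(g$group, c("misc. products", "product A"))
  expect_identical(g$subtotal_risk, c(5857, 4546))
  expect_equal(floor(g$subtotal_percent * 100 + 0.5) / 100, c(56.30, 43.70))
  expect_identical(rep$total_risk, 10403)
})

test_that("truncate mode floors entry risks before both subtotaling and normalization", {
  rep <- apportion(example_history(), example_config("truncate"))
  # 1966/10-month row: exact risk 1140.833...; the published 10.96% only
  # arises as 1140 / 10403 (ratio of truncated integers)
  row <- rep$entries[rep$entries$year == 1966 & rep$entries$months == 10, ]
  expect_equal(row$percent, 1140 / 10403 * 100, tolerance = 1e-12)

  exact <- apportion(example_history(), example_config("exact"))
  expect_gt(exact$total_risk, rep$total_risk)  # nothing discarded
})

test_that("a single entry always receives 100 percent", {
  rep <- apportion(exposure_history(1980, 3, 0.7, 35), case_config(2013))
  expect_equal(rep$entries$percent, 100, tolerance = 1e-12)
  expect_equal(rep$groups$subtotal_percent, 100, tolerance = 1e-12)
})

test_that("percentages are invariant to global scaling of any one factor", {
  cfg <- case_config(2013)
  for (seed in 1:10) {
    h <- generate_history(seed, 20, c(1950, 2000), 2013, n_groups = 4)
    base <- apportion(h, cfg)
    for (col in c("concentration", "potency", "months")) {
      scaled <- h
      k <- if (col == "months") 0.5 else 7
      scaled[[col]] <- scaled[[col]] * k
      expect_equal(apportion(scaled, cfg)$entries$percent,
                   base$entries$percent, tolerance = 1e-9)
    }
  }
})

test_that("percentages conserve to 100 and input order does not matter", {
  cfg <- case_config(2013)
  for (seed in 1:10) {
    h <- generate_history(seed, 30, c(1950, 2000), 2013, n_groups = 3)
    rep <- apportion(h, cfg)
    expect_equal(sum(rep$entries$percent), 100, tolerance = 1e-9)
    expect_equal(sum(rep$groups$subtotal_percent), 100, tolerance = 1e-9)
    expect_equal(rep$groups$subtotal_risk,
                 as.numeric(tapply(rep$entries$risk,
                                   factor(rep$entries$group, rep$groups$group),
                                   sum)),
                 tolerance = 1e-9)
    expect_equal(rep$total_risk, sum(rep$groups$subtotal_risk),
                 tolerance = 1e-9)

    set.seed(seed)
    shuffled <- h[sample(nrow(h)), , drop = FALSE]
    rep2 <- apportion(shuffled, cfg, group_order = "label")
    rep1 <- apportion(h, cfg, group_order = "label")
    # identical rows get identical risks/percents; compare under a
    # canonical key since tied (group, year) rows may swap positions
    canon <- function(r) {
      e <- r$entries
      e[order(e$group, e$year, e$months, e$concentration, e$potency), ]
    }
    e1 <- canon(rep1); e2 <- canon(rep2)
    expect_equal(e2$risk, e1$risk, tolerance = 0)
    expect_equal(e2$percent, e1$percent, tolerance = 0)
    expect_identical(rep2$groups$group, rep1$groups$group)
    expect_equal(rep2$groups$subtotal_percent, rep1$groups$subtotal_percent,
                 tolerance = 0)
  }
})

test_that("shifting diagnosis and every exposure year together changes nothing", {
  cfg <- case_config(2013)
  for (seed in 1:5) {
    h <- generate_history(seed, 15, c(1950, 2000), 2013)
    base <- apportion(h, cfg)
    for (k in c(-20, 7, 100)) {
      shifted <- h
      shifted$year <- shifted$year + k
      rep <- apportion(shifted, case_config(2013 + k))
      expect_equal(rep$entries$risk, base$entries$risk, tolerance = 1e-9)
      expect_equal(rep$entries$percent, base$entries$percent,
                   tolerance = 1e-9)
    }
  }
})

test_that("apportionment agrees with brute-force recomputation on random histories", {
  for (seed in 1:20) {
    h <- generate_history(seed, 5 + seed %% 46, c(1950, 2000), 2013,
                          n_groups = 1 + seed %% 5)
    for (truncate in c(FALSE, TRUE)) {
      cfg <- case_config(2013,
                         rounding = if (truncate) "truncate" else "exact")
      rep <- apportion(h, cfg)
      ora <- oracle_apportion(h, 2013, truncate = truncate)
      idx <- match(paste(rep$entries$year, rep$entries$months,
                         rep$entries$concentration, rep$entries$potency),
                   paste(h$year, h$months, h$concentration, h$potency))
      expect_equal(rep$entries$risk, ora$risk[idx], tolerance = 1e-9)
      expect_equal(rep$entries$percent, ora$percent[idx], tolerance = 1e-9)
    }
  }
})

test_that("group labels are trimmed, case-sensitive, and blanks fall into an explicit bucket", {
  h <- exposure_history(c(1960, 1961, 1962, 1963), 12, 1, 1,
                        group = c(" Product A ", "Product A", "product a", ""))
  rep <- apportion(h, case_config(2013))
  expect_setequal(rep$groups$group,
                  c("Product A", "product a", "(ungrouped)"))
  expect_identical(rep$groups$n_entries[rep$groups$group == "Product A"], 2L)
  # first appearance vs alphabetical ordering
  expect_identical(apportion(h, case_config(2013))$groups$group[1], "Product A")
  expect_identical(apportion(h, case_config(2013), group_order = "label")$groups$group,
                   sort(rep$groups$group))
})

test_that("degenerate histories are rejected with informative errors", {
  expect_error(apportion(example_history()[0, ], case_config(2013)),
               "nothing to apportion")
  expect_error(
    suppressWarnings(
      apportion(exposure_history(c(2010, 2012), 6, 1, 1), case_config(2013))),
    "cannot apportion")
})

test_that("potency sensitivity reruns match hand recomputation and leave inputs untouched", {
  h <- example_history()
  cfg <- example_config("exact")
  base <- apportion(h, cfg)

  out <- sensitivity_over_potency(h, cfg, list(
    identity = c("product A" = 1),
    amphibole = c("product A" = 50 / 6)
  ))
  expect_identical(names(out), c("identity", "amphibole"))
  expect_equal(out$identity$entries$percent, base$entries$percent,
               tolerance = 1e-12)

  # hand recomputation under the override: product A rows get potency 50
  mod <- h
  mod$potency[mod$group == "product A"] <- mod$potency[mod$group == "product A"] * 50 / 6
  ora <- oracle_apportion(mod, 2013)
  pa <- out$amphibole$groups
  expect_equal(pa$subtotal_percent[pa$group == "product A"],
               sum(ora$percent[mod$group == "product A"]), tolerance = 1e-9)
  expect_identical(h$potency, example_history()$potency)  # not mutated

  expect_error(sensitivity_over_potency(h, cfg, c("no such group" = 2)),
               "unknown group")
  expect_error(sensitivity_over_potency(h, cfg, c("product A" = -1)),
               "positive")
})
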