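test_that("the elementary comparison operations are exact arithmetic", {
  expect_identical(cases_prevented(3233, 3113), 120)
  expect_identical(cases_prevented(3233, 3233), 0)
  expect_identical(cases_prevented(3233, 1879), 1354)
  # never clipped
  expect_identical(cases_prevented(100, 130), -30)

  expect_identical(proportion_prevented(120, 3233), 3.7)
  expect_identical(proportion_prevented(0, 3233), 0)
  expect_identical(proportion_prevented(1499, 3233), 46.4)
  expect_error(proportion_prevented(1, 0), "baseline")

  expect_identical(life_years_saved(5635, 5355), 280)
  expect_identical(life_years_saved(5635, 5635), 0)
  expect_identical(life_years_saved(5635, 2996), 2639)

  expect_identical(additional_cost(264303185, 225515010), 38788175)
  expect_identical(additional_cost(5, 5), 0)
})

test_that("percent rounding is half-up at one decimal", {
  # 0.05 rounds up, where round-half-to-even would give 0.0
  expect_identical(proportion_prevented(5, 10000), 0.1)
  expect_identical(proportion_prevented(15, 10000), 0.2)
})

test_that("ICERs carry dominance flags and are antisymmetric", {
  a <- list(total_cost = 100, effect = 10)
  b <- list(total_cost = 150, effect = 8)
  ic <- icer(a, b)
  expect_equal(ic$value, -25)
  expect_identical(ic$flag, "dominant")
  rev <- icer(b, a)
  expect_equal(rev$value, -25)
  expect_identical(rev$flag, "dominated")
  # swapping the comparison leaves the ratio unchanged (numerator and
  # denominator both flip sign) while the dominance flag reverses
  set.seed(1)
  for (i in 1:20) {
    x <- list(total_cost = runif(1, 0, 1e6), effect = runif(1, 0, 100))
    y <- list(total_cost = runif(1, 0, 1e6), effect = runif(1, 0, 100))
    xy <- icer(x, y); yx <- icer(y, x)
    expect_equal(xy$value, yx$value, tolerance = 1e-12)
    if (xy$flag == "dominant") expect_identical(yx$flag, "dominated")
    if (xy$flag == "dominated") expect_identical(yx$flag, "dominant")
  }
  # equal effectiveness: undefined, no division
  same <- icer(a, list(total_cost = 70, effect = 10))
  expect_true(is.na(same$value))
  expect_identical(same$flag, "undefined")
})

test_that("cost per life year saved handles the undefined baseline column", {
  expect_equal(cost_per_life_year_saved(264303185, 280), 264303185 / 280)
  expect_identical(cost_per_life_year_saved(0, 10), 0)
  und <- cost_per_life_year_saved(100, 0)
  expect_true(is.na(und))
  expect_identical(attr(und, "flag"), "undefined")
})

test_that("the comparison table requires a baseline and ignores input order", {
  outs <- reference_totals()
  expect_error(comparison_table(outs[-1]), "baseline")
  cmp <- comparison_table(outs)
  cmp_perm <- comparison_table(rev(outs))
  expect_identical(cmp, cmp_perm)
  expect_identical(cmp$table$strategy, crc_strategies())
  # baseline-only: derived rows zero or undefined
  solo <- comparison_table(outs[1])
  expect_identical(solo$table$cases_prevented, 0)
  expect_identical(solo$table$additional_cost, 0)
  expect_true(is.na(solo$table$cost_per_lys))
  expect_true(is.na(solo$table$icer_vs_none))
})

test_that("dominance flags are symmetric-consistent across the matrix", {
  fl <- cached_base_model()$comparison$icer_flags
  for (i in rownames(fl)) {
    for (j in colnames(fl)) {
      if (fl[i, j] == "dominant") expect_identical(fl[j, i], "dominated")
      if (fl[i, j] == "dominated") expect_identical(fl[j, i], "dominant")
    }
  }
})

test_that("derived rows agree whether computed from ledgers or from totals", {
  fit <- cached_base_model()
  tab <- fit$comparison$table
  for (s in c("fit_ai", "colo")) {
    tr <- fit$traces[[s]]
    tr0 <- fit$traces$none
    row <- tab[tab$strategy == s, ]
    expect_equal(row$life_years_saved,
                 sum(tr0$lyl_disc) - sum(tr$lyl_disc), tolerance = 1e-6)
    expect_equal(row$additional_cost,
                 sum(colSums(fit$costs[[s]]$ledger[, -(1:2)])) -
                   sum(colSums(fit$costs$none$ledger[, -(1:2)])),
                 tolerance = 1e-6)
  }
})

test_that("comparisons export to CSV and JSON", {
  cmp <- comparison_table(reference_totals())
  f <- withr::local_tempfile(fileext = ".csv")
  write_comparison(cmp, f)
  back <- read.csv(f)
  expect_identical(back$strategy, cmp$table$strategy)
  expect_equal(back$total_cost, cmp$table$total_cost)
  fj <- withr::local_tempfile(fileext = ".json")
  write_comparison(cmp, fj)
  js <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(js$table$cases_prevented, cmp$table$cases_prevented)
})
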