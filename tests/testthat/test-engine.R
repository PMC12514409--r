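test_that("with zero incidence there is no cancer, only screening activity", {
  cfg <- one_band_config(0)
  lt <- cached_life_table()
  tr <- run_cohort(cfg, "fit_colo", lt)
  expect_equal(sum(tr$newdx_total), 0)
  expect_equal(sum(tr$deaths_crc), 0)
  expect_equal(sum(tr$lyl), 0)
  expect_gt(sum(tr$fits), 0)
  expect_gt(sum(tr$colo_total), 0)
  costs <- accumulate_costs(tr)
  expect_equal(costs$care_stage1 + costs$care_stage2 +
                 costs$care_stage3 + costs$care_stage4, 0)
  expect_gt(costs$fit, 0)
})

test_that("the no-screening recursion matches its geometric closed form", {
  # zero other-cause mortality and a single incidence band: the susceptible
  # pool decays as S(t+1) = S(t) (1 - h)
  h <- 200e-5
  cfg <- one_band_config(200)
  lt <- flat_life_table(0, 50:100)
  tr <- run_cohort(cfg, "none", lt)
  n_cyc <- nrow(tr)
  expected_cases <- 1e5 * (1 - (1 - h)^n_cyc)
  expect_equal(sum(tr$newdx_total), expected_cases, tolerance = 1e-9)
  # per-cycle diagnoses follow the same recurrence
  expect_equal(tr$newdx_total, 1e5 * (1 - h)^(0:(n_cyc - 1)) * h,
               tolerance = 1e-9)
})

test_that("mass is conserved every cycle in every strategy", {
  fit <- cached_base_model()
  for (s in fit$strategies) {
    tr <- fit$traces[[s]]
    total <- tr$alive +
      cumsum(tr$deaths_other + tr$deaths_crc + tr$deaths_perf)
    expect_equal(total, rep(1e5, nrow(tr)), tolerance = 1e-6)
    expect_true(all(as.matrix(tr) >= -1e-9))
  }
})

test_that("everyone is absorbed by the life-table closing age", {
  fit <- cached_base_model()
  for (s in fit$strategies) {
    expect_equal(tail(fit$traces[[s]]$alive, 1), 0, tolerance = 1e-9)
  }
})

test_that("raising the incidence reduction never increases cases", {
  lt <- cached_life_table()
  cases <- vapply(c(0.3, 0.442, 0.6, 0.9), function(eff) {
    cfg <- config_set(crc_basecase(), "efficacy.colonoscopy", eff)
    sum(run_cohort(cfg, "colo", lt)$newdx_total)
  }, numeric(1))
  expect_true(all(diff(cases) < 0))
})

test_that("screening with zero uptake is no screening", {
  cfg <- config_set(crc_basecase(), "compliance.fit", 0)
  lt <- cached_life_table()
  none <- run_cohort(cfg, "none", lt)
  fit0 <- run_cohort(cfg, "fit_colo", lt)
  for (col in c("newdx_total", "deaths_crc", "deaths_other", "lyl", "lyl_disc")) {
    expect_equal(fit0[[col]], none[[col]], tolerance = 1e-12, info = col)
  }
  expect_equal(sum(fit0$fits), 0)
  expect_equal(sum(fit0$colo_total), 0)
})

test_that("diagnosed patients exit to cured after surviving the cure window", {
  # deterministic-ish check: with zero stage mortality everyone diagnosed is
  # eventually cured, never dying of cancer
  cfg <- crc_basecase()
  cfg$stages$annual_mortality <- c(0, 0, 0, 0)
  lt <- flat_life_table(0, 50:100)
  tr <- run_cohort(cfg, "none", lt)
  expect_equal(sum(tr$deaths_crc), 0)
  expect_equal(tail(tr$cured, 1) + tail(tr$diagnosed, 1), sum(tr$newdx_total),
               tolerance = 1e-9)
  # ... and with certain stage mortality nobody reaches the cured state
  cfg$stages$annual_mortality <- c(1, 1, 1, 1)
  tr <- run_cohort(cfg, "none", lt)
  expect_equal(tail(tr$cured, 1), 0)
  expect_equal(sum(tr$deaths_crc), sum(tr$newdx_total) - tail(tr$diagnosed, 1),
               tolerance = 1e-9)
})

test_that("life-years-lost accrual scales deaths by residual expectancy", {
  lt <- cached_life_table()
  expect_equal(life_years_lost_accrual(0, 60, lt, 0.03, 10),
               c(undiscounted = 0, discounted = 0))
  ex <- residual_life_expectancy(lt, 60)
  acc <- life_years_lost_accrual(10, 60, lt, 0.03, 10)
  expect_equal(unname(acc["undiscounted"]), 10 * ex, tolerance = 1e-12)
  expect_lt(acc["discounted"], acc["undiscounted"])
  acc0 <- life_years_lost_accrual(10, 60, lt, 0, 10)
  expect_equal(unname(acc0["discounted"]), unname(acc0["undiscounted"]),
               tolerance = 1e-12)
})

test_that("therapeutic share of colonoscopies equals the polypectomy rate", {
  fit <- cached_base_model()
  for (s in c("fit_colo", "colo")) {
    tr <- fit$traces[[s]]
    expect_equal(sum(tr$colo_ther) / sum(tr$colo_total), 0.73,
                 tolerance = 1e-9)
  }
})

test_that("the engine rejects invalid inputs by name", {
  cfg <- crc_basecase()
  cfg$tests$fit_sensitivity <- 2
  expect_error(run_cohort(cfg, "none"), "fit_sensitivity")
  short_lt <- flat_life_table(0.01, 50:80)
  expect_error(run_cohort(crc_basecase(), "none", short_lt), "shorter")
  expect_error(run_cohort(crc_basecase(), "nonsense"))
})

test_that("traces export to tidy long format", {
  tr <- cached_base_model()$traces$none
  long <- trace_long(tr)
  expect_identical(nrow(long), nrow(tr) * (ncol(tr) - 2L))
  expect_named(long, c("cycle", "age", "measure", "value"))
  sub <- long[long$measure == "newdx_total", ]
  expect_equal(sub$value, tr$newdx_total)
})

test_that("the microsimulation is seed-reproducible and degenerates exactly", {
  cfg <- one_band_config(0)
  cfg$economics$cohort_size <- 1000
  lt <- flat_life_table(0, 50:100)
  ms <- microsim_oracle(cfg, "none", lt, n = 500, seed = 42)
  expect_identical(ms$cases, 0)
  expect_identical(ms$lyl, 0)
  expect_identical(ms$fits, 0)
  a <- microsim_oracle(crc_basecase(), "fit_ai", cached_life_table(),
                       n = 2000, seed = 7)
  b <- microsim_oracle(crc_basecase(), "fit_ai", cached_life_table(),
                       n = 2000, seed = 7)
  expect_identical(a, b)
})

test_that("simulate() returns one microsimulation row per strategy", {
  fit <- cached_base_model()
  sim <- simulate(fit, nsim = 500, seed = 3)
  expect_identical(sim$strategy, fit$strategies)
  expect_true(all(sim$cases >= 0))
})
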