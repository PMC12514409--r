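test_that("a single-point sweep at the base value reproduces the base run", {
  cfg <- crc_basecase()
  lt <- cached_life_table()
  base <- cached_base_model()
  sw <- one_way_sweep(cfg, "compliance.fit", cfg$compliance$fit,
                      life_table = lt)
  base_tab <- base$comparison$table
  for (col in c("crc_cases", "cancer_lyl", "total_cost", "icer_vs_none")) {
    expect_equal(sw[[col]], base_tab[[col]], tolerance = 1e-12, info = col)
  }
  # 1x1 two-way grid likewise
  tw <- two_way_sweep(cfg, "tests.fit_sensitivity", 0.73,
                      "tests.fit_specificity", 0.919, life_table = lt)
  expect_equal(tw$total_cost, base_tab$total_cost, tolerance = 1e-12)
})

test_that("sweep grids are validated", {
  cfg <- crc_basecase()
  expect_error(one_way_sweep(cfg, "compliance.fit", numeric(0)), "non-empty")
  expect_error(one_way_sweep(cfg, "compliance.fit", c(0.1, 0.3, 0.2)),
               "monotone")
  expect_error(one_way_sweep(cfg, "not.a.path", c(0.1, 0.2)), "resolve")
})

test_that("threshold detection interpolates sign changes", {
  # one-signed curve: no crossing
  expect_length(find_threshold(1:5, c(1, 2, 1, 3, 2)), 0)
  # symmetric flip between -1 and 1: the midpoint
  expect_equal(find_threshold(c(0, 1), c(-1, 1)), 0.5)
  # linear curve y = x - 0.4 on a coarse grid: exact root
  g <- seq(0, 1, by = 0.2)
  expect_equal(find_threshold(g, g - 0.4), 0.4, tolerance = 1e-12)
  # multiple flips are all reported, in order
  th <- find_threshold(0:3, c(-1, 1, -1, 1))
  expect_equal(th, c(0.5, 1.5, 2.5))
})

test_that("ICER falls monotonically as joint compliance rises", {
  sw <- one_way_sweep(crc_basecase(), "compliance.all", seq(0.1, 1, by = 0.1),
                      life_table = cached_life_table())
  for (s in c("fit_colo", "fit_ai", "colo", "ai_colo")) {
    curve <- icer_curve(sw, s)
    expect_true(all(diff(curve$icer) < 0), info = s)
  }
  # the AI follow-up arm stays the cheapest per life year throughout
  expect_true(all(icer_curve(sw, "fit_ai")$icer <
                    icer_curve(sw, "fit_colo")$icer))
})

test_that("FIT-arm ICER rises as FIT specificity falls", {
  sw <- one_way_sweep(crc_basecase(), "tests.fit_specificity",
                      seq(0.20, 0.919, length.out = 8),
                      strategies = c("none", "fit_colo", "fit_ai"),
                      life_table = cached_life_table())
  for (s in c("fit_colo", "fit_ai")) {
    curve <- icer_curve(sw, s)  # grid ascends in specificity
    expect_true(all(diff(curve$icer) < 0), info = s)
  }
})

test_that("FIT+AI keeps the lower ICER across the FIT-sensitivity grid", {
  sw <- one_way_sweep(crc_basecase(), "tests.fit_sensitivity",
                      seq(0.40, 0.73, length.out = 8),
                      strategies = c("none", "fit_colo", "fit_ai"),
                      life_table = cached_life_table())
  expect_true(all(icer_curve(sw, "fit_ai")$icer <
                    icer_curve(sw, "fit_colo")$icer))
})

test_that("colonoscopy cost moves direct-arm ICERs faster than FIT arms", {
  grid <- 1259 * c(0.5, 1, 2)
  sw <- one_way_sweep(crc_basecase(), "costs.colonoscopy", grid,
                      life_table = cached_life_table())
  slope <- function(s) {
    cv <- icer_curve(sw, s)
    (cv$icer[3] - cv$icer[1]) / (grid[3] - grid[1])
  }
  expect_gt(slope("colo"), slope("fit_colo"))
  expect_gt(slope("ai_colo"), slope("fit_ai"))
})

test_that("two-way FIT performance sweep is a full Cartesian grid", {
  sw <- two_way_sweep(crc_basecase(),
                      "tests.fit_sensitivity", c(0.5, 0.73),
                      "tests.fit_specificity", c(0.6, 0.919),
                      strategies = c("none", "fit_ai"),
                      life_table = cached_life_table())
  expect_identical(nrow(sw), 2L * 2L * 2L)
  combos <- unique(sw[, c("value_a", "value_b")])
  expect_identical(nrow(combos), 4L)
})
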