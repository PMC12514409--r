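# minimal hand-built trace for desk arithmetic on the costing rules
stub_trace <- function(cycles = 0:2, ...) {
  cols <- list(...)
  tr <- data.frame(cycle = cycles, age = 50 + cycles,
                   fits = 0, colo_total = 0, colo_ther = 0, bleeding = 0,
                   perforation = 0, newdx_s1 = 0, newdx_s2 = 0, newdx_s3 = 0,
                   newdx_s4 = 0)
  for (nm in names(cols)) tr[[nm]] <- cols[[nm]]
  tr
}

test_that("discount factors match their closed forms", {
  expect_identical(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(25, 0.03), 1.03^-25, tolerance = 1e-12)
  expect_identical(discount_factor(10, 0), 1)
  expect_error(discount_factor(-1, 0.03))
})

test_that("cost categories follow the attachment rules", {
  costs <- crc_basecase()$costs
  # an empty trace costs nothing
  cb <- accumulate_costs(stub_trace(), costs, r = 0.03)
  expect_equal(cb$total, 0)
  # one colonoscopy at t = 0, consultation folded out: exactly the unit cost
  cb <- accumulate_costs(stub_trace(colo_total = c(1, 0, 0)), costs, r = 0.03,
                         consultation_per_colonoscopy = FALSE)
  expect_equal(cb$colonoscopy, 1259, tolerance = 1e-12)
  expect_equal(cb$total, 1259, tolerance = 1e-12)
  # with the consultation fee attached per attendance
  cb <- accumulate_costs(stub_trace(colo_total = c(1, 0, 0)), costs, r = 0.03,
                         consultation_per_colonoscopy = TRUE)
  expect_equal(cb$colonoscopy, 1259 + 96, tolerance = 1e-12)
  # one stage-4 diagnosis at t = 1 discounts by one year: 45,115 / 1.03
  cb <- accumulate_costs(stub_trace(newdx_s4 = c(0, 1, 0)), costs, r = 0.03)
  expect_equal(cb$care_stage4, 45115 / 1.03, tolerance = 1e-12)
  # histopathology per therapeutic colonoscopy lands in the polypectomy row
  cb <- accumulate_costs(stub_trace(colo_total = c(2, 0, 0),
                                    colo_ther = c(2, 0, 0)), costs, r = 0)
  expect_equal(cb$polypectomy, 2 * 142, tolerance = 1e-12)
  cb <- accumulate_costs(stub_trace(colo_total = c(2, 0, 0),
                                    colo_ther = c(2, 0, 0)), costs, r = 0,
                         histopathology_per_therapeutic = FALSE)
  expect_equal(cb$polypectomy, 0)
})

test_that("zero discounting equals undiscounted totals on a real trace", {
  cfg <- crc_basecase()
  cfg$economics$discount_rate <- 0
  lt <- cached_life_table()
  tr <- run_cohort(cfg, "fit_colo", lt)
  cb <- accumulate_costs(tr)
  manual <- sum(tr$fits) * 19 + sum(tr$colo_total) * (1259 + 96) +
    sum(tr$colo_ther) * 142 + sum(tr$bleeding) * 3320 +
    sum(tr$perforation) * 10790 + sum(tr$newdx_s1) * 17071 +
    sum(tr$newdx_s2) * 19755 + sum(tr$newdx_s3) * 26883 +
    sum(tr$newdx_s4) * 45115
  expect_equal(cb$total, manual, tolerance = 1e-9)
  # r = 0 makes the lost-life-year ledgers coincide too
  expect_equal(tr$lyl, tr$lyl_disc, tolerance = 1e-9)
})

test_that("the breakdown is internally consistent and additive over cycles", {
  fit <- cached_base_model()
  cb <- fit$costs$fit_ai
  cats <- setdiff(names(cb), c("total", "ledger"))
  expect_equal(sum(unlist(cb[cats])), cb$total, tolerance = 1e-6)
  # ledger sums reproduce the category totals
  for (ct in cats) {
    expect_equal(sum(cb$ledger[[ct]]), cb[[ct]], tolerance = 1e-9, info = ct)
  }
  # additivity across disjoint cycle ranges
  led <- cb$ledger
  first <- led$cycle < 10
  expect_equal(sum(led$colonoscopy[first]) + sum(led$colonoscopy[!first]),
               cb$colonoscopy, tolerance = 1e-9)
})

test_that("total cost is monotone in unit costs", {
  lt <- cached_life_table()
  tr <- run_cohort(crc_basecase(), "colo", lt)
  base <- accumulate_costs(tr)$total
  costs2 <- crc_basecase()$costs
  costs2$colonoscopy <- costs2$colonoscopy * 1.5
  expect_gt(accumulate_costs(tr, costs2)$total, base)
  costs3 <- crc_basecase()$costs
  costs3$care_stage4 <- costs3$care_stage4 * 2
  expect_gt(accumulate_costs(tr, costs3)$total, base)
})
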