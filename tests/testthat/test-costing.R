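test_that("uninsured cost inverts the proportion-of-total definition", {
  # 29.5% of a 1,000 total is 295 uninsured against 705 insured (outpatient
  # likewise with 15.2%/848)
  expect_equal(uninsured_cost(705, 848), 447, tolerance = 1e-9)
  expect_equal(uninsured_cost(0, 0), 0)
  expect_equal(uninsured_cost(1000, 0), 1000 * 0.295 / 0.705)
  expect_equal(uninsured_cost(1000, 0), 418.4, tolerance = 1e-4)
  expect_error(uninsured_cost(-1, 0), "nonnegative")
})

test_that("caregiver cost values days, third-days, and elderly companions", {
  expect_equal(caregiver_cost(10, 0, 0, patient_age = 50), 568.09)
  expect_equal(caregiver_cost(0, 3, 0, patient_age = 50), 56.809)
  young <- caregiver_cost(0, 2, 1, patient_age = 50)
  old <- caregiver_cost(0, 2, 1, patient_age = 70)
  expect_equal(old - young, 2.896 + 2 * 0.891)
  expect_error(caregiver_cost(-1, 0, 0, patient_age = 50), "nonnegative")
})

test_that("transport cost is round trips times published unit costs", {
  expect_equal(transport_cost(0, 0), 0)
  expect_equal(transport_cost(10, 1), 11.806)
  expect_equal(transport_cost(1, 0), 0.891)
})

test_that("second-year out-of-pocket spending applies the published ratio", {
  expect_equal(second_year_out_of_pocket(1000, 0.13), 130)
  expect_equal(second_year_out_of_pocket(1000, 0.38), 380)
  expect_equal(second_year_out_of_pocket(0, 0.2), 0)
  expect_error(second_year_out_of_pocket(1000, 0.5), "range")
})

test_that("human-capital premature cost sums wages over truncated PYLL", {
  expect_equal(human_capital_premature_cost("male", 65, life_fix, wage_fix), 0)
  expect_equal(human_capital_premature_cost("male", 70, life_fix, wage_fix), 0)
  # PYLL at 45 exceeds 20 years, so earnings run to retirement
  flat <- validate_wage_table(data.frame(
    gender = rep(c("male", "female"), each = 5),
    band = rep(stroke_bands(), 2), annual_wage = 100))
  expect_equal(human_capital_premature_cost("male", 45, life_fix, flat),
               20 * 100)
  # truncation at retirement: two years of the 55-64 band wage
  expect_equal(human_capital_premature_cost("male", 63, life_fix, wage_fix),
               2 * 14123.0)
  expect_error(human_capital_premature_cost("male", 44, life_fix, wage_fix),
               "45")
})

test_that("synthetic wage schedule reproduces the published premature costs", {
  got <- vapply(c("male", "female"), function(g) {
    c(human_capital_premature_cost(g, 45, life_fix, wage_fix),
      human_capital_premature_cost(g, 55, life_fix, wage_fix))
  }, numeric(2))
  expect_equal(got[, "male"], c(521179, 141230))
  expect_equal(got[, "female"], c(171802, 54111))
})

test_that("absenteeism cost uses daily and hourly wages and stops at retirement", {
  expect_equal(absenteeism_cost(5, 0, age = 50), 284.045)
  expect_equal(absenteeism_cost(0, 8, age = 50), 56.809)
  expect_equal(absenteeism_cost(5, 10, age = 70), 0)
  expect_equal(absenteeism_cost(0, 0, age = 50), 0)
})

test_that("friction premature cost is the friction-period wage plus training", {
  expect_equal(training_cost_krw(cfg_fix), 362 * 1.293 * 1.2)
  expect_equal(training_cost_krw(cfg_fix), 561.7, tolerance = 1e-4)
  expect_equal(friction_premature_cost("male", 70, wage_fix, cfg_fix), 0)
  w24 <- validate_wage_table(data.frame(
    gender = rep(c("male", "female"), each = 5),
    band = rep(stroke_bands(), 2), annual_wage = 24000))
  expect_equal(friction_premature_cost("male", 50, w24, cfg_fix),
               12000 + 362 * 1.293 * 1.2)
})

test_that("friction valuation never exceeds human-capital valuation", {
  for (seed in 1:6) {
    sc <- generate_scenario(seed)
    for (g in c("male", "female")) {
      for (a in c(45, 50, 55, 60, 64)) {
        fr <- friction_premature_cost(g, a, sc$wage, sc$config)
        hc <- human_capital_premature_cost(g, a, sc$life, sc$wage)
        expect_lte(fr, hc)
      }
    }
  }
})

test_that("assembly operations are homogeneous of degree one in money", {
  lam <- 3.7
  expect_equal(uninsured_cost(705 * lam, 848 * lam), 447 * lam)
  w <- wage_inputs(daily_wage = 56.809 * lam,
                   transport_outpatient = 0.891 * lam,
                   transport_admission = 2.896 * lam)
  expect_equal(caregiver_cost(10, 3, 1, patient_age = 70, wages = w),
               lam * caregiver_cost(10, 3, 1, patient_age = 70))
  expect_equal(transport_cost(10, 1, wages = w), lam * transport_cost(10, 1))
  expect_equal(second_year_out_of_pocket(1000 * lam, 0.2),
               lam * second_year_out_of_pocket(1000, 0.2))
  scaled <- as.data.frame(wage_fix)
  scaled$annual_wage <- scaled$annual_wage * lam
  scaled <- validate_wage_table(scaled)
  expect_equal(human_capital_premature_cost("male", 45, life_fix, scaled),
               lam * human_capital_premature_cost("male", 45, life_fix,
                                                  wage_fix))
})
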