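test_that("cohort trace starts from first-year case fatality and conserves mass", {
  tr <- run_cohort("male", 85, epi_fix, cost_fix, cfg_fix)
  expect_equal(tr$alive[1], 0.3431)   # one-year survival of the 85+ band
  expect_equal(tr$alive + tr$dead, rep(1, nrow(tr)), tolerance = 1e-12)
  expect_true(all(diff(tr$alive) <= 0))
  expect_equal(nrow(tr), 99 - 85 + 1)

  tr45 <- run_cohort("female", 45, epi_fix, cost_fix, cfg_fix)
  expect_equal(tr45$alive[1], 0.8290)
  expect_equal(nrow(tr45), 55)
  # within-cycle event fractions never exceed the entering alive fraction
  events <- tr45$frac_nonfatal_recurrence + tr45$frac_fatal_recurrence +
    tr45$frac_nonstroke_death + tr45$frac_stay
  expect_true(all(events <= tr45$entering_alive + 1e-12))
  expect_true(all(events >= 0))
  expect_error(run_cohort("male", 50, epi_fix, cost_fix, cfg_fix),
               "onset_age")
})

test_that("an immortal cohort survives every cycle and earns the truncation bound", {
  tr <- run_cohort("male", 45, immortal_epi(), cost_fix, cfg_fix)
  expect_equal(tr$alive, rep(1, 55))
  # one completed year per post-acute cycle: terminal_age - onset_age
  expect_equal(life_expectancy(tr), 54)
})

test_that("raising any death rate never raises life expectancy", {
  base <- life_expectancy(run_cohort("female", 55, epi_fix, cost_fix, cfg_fix))
  df <- as.data.frame(epi_fix)
  df$nonstroke_mortality_general <- df$nonstroke_mortality_general * 3
  worse <- life_expectancy(run_cohort("female", 55, validate_epi_table(df),
                                      cost_fix, cfg_fix))
  expect_lte(worse, base)
  df2 <- as.data.frame(epi_fix)
  df2$first_year_survival <- pmax(df2$first_year_survival - 0.2, 0.05)
  worse2 <- life_expectancy(run_cohort("female", 55, validate_epi_table(df2),
                                       cost_fix, cfg_fix))
  expect_lte(worse2, base)
  cfg_hi <- stroke_config(smr_female = 2.295 * 2)
  expect_lte(life_expectancy(run_cohort("female", 55, epi_fix, cost_fix,
                                        cfg_hi)), base)
})

test_that("years of life lost and percent reduction follow their definitions", {
  y <- years_of_life_lost(16.59, 32.16)
  expect_equal(y$yll, 15.57)
  expect_equal(y$reduction_pct, 100 * 15.57 / 32.16)
  y2 <- years_of_life_lost(0.75, 6.28)
  expect_equal(y2$yll, 5.53)
  expect_equal(y2$reduction_pct, 88.06, tolerance = 1e-3)
  expect_equal(years_of_life_lost(10, 10), list(yll = 0, reduction_pct = 0))
  expect_error(years_of_life_lost(1, 0), "positive")
})

test_that("lifetime costs: null costs, retirement bands and exact additivity", {
  tr0 <- run_cohort("male", 45, epi_fix, zero_cost_table(), cfg_fix)
  lc0 <- expected_lifetime_cost(tr0)
  expect_equal(lc0$total, 0)
  expect_equal(lc0$excl_premature, 0)

  for (a in c(65, 75, 85)) {
    lc <- expected_lifetime_cost(run_cohort("male", a, epi_fix, cost_fix,
                                            cfg_fix))
    expect_equal(lc$total, lc$excl_premature)  # no premature cost at 65+
  }

  lc45 <- expected_lifetime_cost(run_cohort("female", 45, epi_fix, cost_fix,
                                            cfg_fix))
  expect_identical(lc45$total, lc45$excl_premature + lc45$premature)
  expect_gt(lc45$premature, 0)
})

test_that("friction mode swaps the premature component and needs wages", {
  cfg_fr <- stroke_config(productivity_mode = "friction")
  expect_error(run_cohort("male", 45, epi_fix, cost_fix, cfg_fr), "wage")
  lc_fr <- expected_lifetime_cost(run_cohort("male", 45, epi_fix, cost_fix,
                                             cfg_fr, wage_fix))
  lc_hc <- expected_lifetime_cost(run_cohort("male", 45, epi_fix, cost_fix,
                                             cfg_fix))
  expect_lt(lc_fr$total, lc_hc$total)
  expect_equal(lc_fr$excl_premature, lc_hc$excl_premature)
  # no premature component at/after retirement: modes coincide
  lc_fr65 <- expected_lifetime_cost(run_cohort("male", 65, epi_fix, cost_fix,
                                               cfg_fr, wage_fix))
  lc_hc65 <- expected_lifetime_cost(run_cohort("male", 65, epi_fix, cost_fix,
                                               cfg_fix))
  expect_equal(lc_fr65$total, lc_hc65$total)
})

test_that("lifetime_table assembles all ten cohorts with matched references", {
  lt <- lifetime_table(epi_fix, cost_fix, life_fix, cfg_fix)
  expect_equal(nrow(lt), 10L)
  expect_equal(lt$le_general[lt$gender == "male" & lt$onset_age == 45], 32.16)
  expect_equal(lt$yll, lt$le_general - lt$le_model)
  expect_true(all(lt$cost_total >= lt$cost_excl_premature))
  expect_true(all(lt$reduction_pct > 0 & lt$reduction_pct < 100))
  # lifetime costs fall with onset age within gender
  for (g in c("male", "female")) {
    expect_true(all(diff(lt$cost_total[lt$gender == g]) < 0))
  }
})
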