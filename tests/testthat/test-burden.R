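table4_costs <- function() {
  data.frame(
    gender = rep(c("male", "female"), each = 5),
    onset_age = rep(stroke_bands(), 2),
    cost_total = c(200701, 81914, 16395, 9888, 6543,
                   75698, 39118, 19261, 10846, 6182))
}

test_that("national burden cells, totals and shares are internally consistent", {
  b <- national_burden(epi_fix, table4_costs())
  expect_equal(sum(b$by_cohort$burden), b$total)
  expect_equal(sum(b$by_band$cost_share_pct), 100)
  expect_equal(sum(b$by_band$incidence_share_pct), 100)
  expect_equal(b$by_cohort$burden,
               b$by_cohort$incident_cases * b$by_cohort$cost_total)
  expect_equal(b$cost_share_45_64_pct,
               sum(b$by_band$cost_share_pct[b$by_band$band %in% c(45, 55)]))
})

test_that("a single costed band carries the whole cost share", {
  lc <- table4_costs()
  lc$cost_total[lc$onset_age != 55] <- 0
  b <- national_burden(epi_fix, lc)
  expect_equal(b$by_band$cost_share_pct[b$by_band$band == 55], 100)
  expect_equal(sum(b$by_band$cost_share_pct), 100)
})

test_that("burden totals are invariant to row order and need full coverage", {
  lc <- table4_costs()
  shuffled <- lc[sample(nrow(lc)), ]
  epi_shuffled <- validate_epi_table(as.data.frame(epi_fix))
  b1 <- national_burden(epi_fix, lc)
  b2 <- national_burden(epi_shuffled, shuffled)
  expect_equal(b1$total, b2$total)
  expect_equal(b1$by_band, b2$by_band)
  expect_error(national_burden(epi_fix, lc[-1, ]), "every gender x band")
})

test_that("lifetime cost is exactly linear in the unit costs", {
  lam <- 1.7
  scaled <- as.data.frame(cost_fix)
  for (col in c("cost_first_year", "cost_subsequent_year", "cost_fatal",
                "cost_premature_death")) {
    scaled[[col]] <- scaled[[col]] * lam
  }
  scaled <- validate_cost_table(scaled)
  for (g in c("male", "female")) {
    base <- expected_lifetime_cost(run_cohort(g, 55, epi_fix, cost_fix,
                                              cfg_fix))
    up <- expected_lifetime_cost(run_cohort(g, 55, epi_fix, scaled, cfg_fix))
    expect_equal(up$total, lam * base$total, tolerance = 1e-12)
    expect_equal(up$excl_premature, lam * base$excl_premature,
                 tolerance = 1e-12)
  }
})

test_that("one-way sensitivity brackets the base case as expected", {
  sens <- one_way_sensitivity(epi_fix, cost_fix, life_fix, cfg_fix, wage_fix)
  expect_equal(nrow(sens), 10L)
  expect_true(all(sens$smr_low <= sens$smr_high))
  expect_true(all(sens$cost_low <= sens$base & sens$base <= sens$cost_high))

  # a higher SMR cannot lengthen life
  lt_base <- lifetime_table(epi_fix, cost_fix, life_fix, cfg_fix)
  cfg_hi <- stroke_config(smr_male = 1.914 * 1.2, smr_female = 2.295 * 1.2)
  lt_hi <- lifetime_table(epi_fix, cost_fix, life_fix, cfg_hi)
  expect_true(all(lt_hi$le_model <= lt_base$le_model))

  # with premature costs in scope the +/-20% scenario is exactly linear
  # wherever no premature component exists (onset 65+)
  sens_all <- one_way_sensitivity(epi_fix, cost_fix, life_fix, cfg_fix,
                                  wage_fix, scale_premature = TRUE)
  old <- sens_all$onset_age >= 65
  expect_equal(sens_all$cost_low[old], 0.8 * sens_all$base[old],
               tolerance = 1e-12)
  expect_equal(sens_all$cost_high[old], 1.2 * sens_all$base[old],
               tolerance = 1e-12)

  # friction changes nothing when no premature component applies
  m65 <- sens$gender == "male" & sens$onset_age == 65
  expect_equal(sens$friction[m65], sens$base[m65])
  expect_true(all(sens$friction <= sens$base))
})

test_that("report renderers reproduce the published layouts", {
  lt <- lifetime_table(epi_fix, cost_fix, life_fix, cfg_fix)
  rl <- render_life_table(lt)
  expect_equal(names(rl), c("gender", "onset_age", "le_general",
                            "le_post_stroke", "years_of_life_lost",
                            "reduction_pct"))
  expect_equal(rl$le_general[1], 32.16)
  expect_equal(rl$reduction_pct, round(lt$reduction_pct, 2))
  expect_error(render_life_table(lt[0, ]), "no cohort")

  sens <- one_way_sensitivity(epi_fix, cost_fix, life_fix, cfg_fix, wage_fix)
  rc <- render_cost_table(lt, sens)
  expect_match(rc$base_case[1], "^[0-9,]+ \\([0-9,]+\\)$")
  expect_match(rc$smr_pm20[1], "^[0-9,]+~[0-9,]+$")
  m65 <- rc$gender == "male" & rc$onset_age == 65
  base65 <- lt$cost_total[lt$gender == "male" & lt$onset_age == 65]
  expect_equal(rc$base_case[m65],
               sprintf("%s (%s)", formatC(round(base65), format = "d",
                                          big.mark = ","),
                       formatC(round(base65), format = "d", big.mark = ",")))
})
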