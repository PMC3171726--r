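#' Unit wage and transport inputs
#'
#' Default micro-costing constants, all in thousand KRW (2008 values):
#' the average daily wage of women aged 20-50 (the typical informal
#' caregiver), average round-trip transport costs to a healthcare
#' institution for outpatient visits and admissions, and the hourly wage
#' (daily wage / 8 unless given).
#'
#' @param daily_wage Daily wage, thousand KRW (default 56.809).
#' @param transport_outpatient Round-trip transport per outpatient visit,
#'   thousand KRW (default 0.891).
#' @param transport_admission Round-trip transport per admission,
#'   thousand KRW (default 2.896).
#' @param hourly_wage Hourly wage, thousand KRW (default `daily_wage / 8`).
#' @return A named list of unit costs.
#' @export
wage_inputs <- function(daily_wage = 56.809,
                        transport_outpatient = 0.891,
                        transport_admission = 2.896,
                        hourly_wage = daily_wage / 8) {
  if (any(c(daily_wage, transport_outpatient, transport_admission,
            hourly_wage) < 0)) {
    stop("wage and transport inputs must be nonnegative", call. = FALSE)
  }
  list(daily_wage = daily_wage,
       transport_outpatient = transport_outpatient,
       transport_admission = transport_admission,
       hourly_wage = hourly_wage)
}

#' Insurance-noncovered medical cost
#'
#' The published uninsured proportions (29.5% of total medical cost for
#' admissions, 15.2% for outpatient care) are fractions of the TOTAL
#' medical cost, so the uninsured amount implied by an insured amount is
#' `insured * f / (1 - f)` per care setting.
#'
#' @param insured_inpatient Insured inpatient cost, thousand KRW.
#' @param insured_outpatient Insured outpatient cost, thousand KRW.
#' @param frac_inpatient Uninsured fraction of total inpatient cost
#'   (default 0.295).
#' @param frac_outpatient Uninsured fraction of total outpatient cost
#'   (default 0.152).
#' @return Uninsured cost, thousand KRW. Vectorized.
#' @export
uninsured_cost <- function(insured_inpatient, insured_outpatient,
                           frac_inpatient = 0.295, frac_outpatient = 0.152) {
  if (any(insured_inpatient < 0) || any(insured_outpatient < 0)) {
    stop("insured costs must be nonnegative", call. = FALSE)
  }
  insured_inpatient * frac_inpatient / (1 - frac_inpatient) +
    insured_outpatient * frac_outpatient / (1 - frac_outpatient)
}

#' Informal caregiver cost
#'
#' Hospital days are valued at the full daily wage; an outpatient visit
#' takes one-third of a caregiver day. For patients older than 65 years,
#' who typically attend accompanied, one extra round trip per visit and
#' per admission (the companion's transport) is added.
#'
#' @param inpatient_days Hospital days per year.
#' @param outpatient_visits Outpatient visits per year.
#' @param admissions Admissions per year (companion transport only).
#' @param patient_age Patient age in years.
#' @param wages A [wage_inputs()] list.
#' @return Caregiver cost, thousand KRW per year.
#' @export
caregiver_cost <- function(inpatient_days, outpatient_visits, admissions = 0,
                           patient_age, wages = wage_inputs()) {
  if (any(c(inpatient_days, outpatient_visits, admissions) < 0)) {
    stop("utilization counts must be nonnegative", call. = FALSE)
  }
  out <- inpatient_days * wages$daily_wage +
    outpatient_visits * wages$daily_wage / 3
  companion <- admissions * wages$transport_admission +
    outpatient_visits * wages$transport_outpatient
  out + ifelse(patient_age > 65, companion, 0)
}

#' Patient transport cost
#'
#' Average round-trip transport cost times the number of stroke-related
#' visits and admissions.
#'
#' @param outpatient_visits Outpatient visits per year.
#' @param admissions Admissions per year.
#' @param wages A [wage_inputs()] list.
#' @return Transport cost, thousand KRW per year.
#' @export
transport_cost <- function(outpatient_visits, admissions,
                           wages = wage_inputs()) {
  if (any(c(outpatient_visits, admissions) < 0)) {
    stop("utilization counts must be nonnegative", call. = FALSE)
  }
  outpatient_visits * wages$transport_outpatient +
    admissions * wages$transport_admission
}

#' Out-of-pocket spending beyond the first year
#'
#' Applies the gender/age-specific ratio of second-year to first-year
#' medical costs to first-year out-of-pocket spending; published ratios
#' range from 0.13 to 0.38.
#'
#' @param first_year_oop First-year out-of-pocket spending, thousand KRW.
#' @param ratio Second-to-first-year cost ratio, within `[0.13, 0.38]`.
#' @return Second-year (and beyond) annual out-of-pocket spending,
#'   thousand KRW.
#' @export
second_year_out_of_pocket <- function(first_year_oop, ratio) {
  if (any(ratio < 0.13) || any(ratio > 0.38)) {
    stop("second-year ratio must lie within the published range [0.13, 0.38]",
         call. = FALSE)
  }
  if (any(first_year_oop < 0)) {
    stop("out-of-pocket spending must be nonnegative", call. = FALSE)
  }
  first_year_oop * ratio
}

wage_at_age <- function(wage_table, gender, age) {
  i <- which(wage_table$gender == gender & wage_table$band == band_of_age(age))
  if (length(i) != 1L) {
    stop(sprintf("configuration error: no wage band for (%s, %s)",
                 gender, band_of_age(age)), call. = FALSE)
  }
  wage_table$annual_wage[i]
}

genpop_le_at <- function(life, gender, age) {
  sub <- life[life$gender == gender, ]
  stats::approx(sub$age, sub$life_expectancy, xout = age, rule = 2)$y
}

#' Premature-death productivity cost, human-capital valuation
#'
#' The expected value of future earnings over the potential years of life
#' lost (PYLL), where PYLL is the general-population remaining life
#' expectancy at the age of death. Earnings accrue only up to retirement:
#' annual wages of the gender/age band are summed over ages from the age
#' at death to `min(retirement_age, age_at_death + PYLL)`, with a
#' fractional final year credited proportionally. Zero at or after
#' retirement.
#'
#' @param gender `"male"` or `"female"`.
#' @param age_at_death Age at death in years (`>= 45`).
#' @param life A `life_table` (PYLL lookup; interpolated between the
#'   tabulated ages).
#' @param wage_table A `wage_table` of annual wages, thousand KRW.
#' @param retirement_age Retirement age (default 65).
#' @return Forgone future earnings, thousand KRW.
#' @export
human_capital_premature_cost <- function(gender, age_at_death, life,
                                         wage_table, retirement_age = 65) {
  if (age_at_death < 45) {
    stop("age_at_death below 45 is outside the modelled range", call. = FALSE)
  }
  if (age_at_death >= retirement_age) return(0)
  pyll <- genpop_le_at(life, gender, age_at_death)
  horizon <- min(retirement_age, age_at_death + pyll)
  total <- 0
  a <- age_at_death
  while (a < horizon) {
    step <- min(1, horizon - a)
    total <- total + step * wage_at_age(wage_table, gender, a)
    a <- a + 1
  }
  total
}

#' Productivity cost of absence from work
#'
#' Hospitalization days are valued at the daily wage and outpatient hours
#' at the hourly wage; zero at or after retirement.
#'
#' @param inpatient_days Hospitalization days.
#' @param outpatient_hours Hours spent on outpatient visits.
#' @param wages A [wage_inputs()] list.
#' @param age Patient age in years.
#' @param retirement_age Retirement age (default 65).
#' @return Absenteeism cost, thousand KRW.
#' @export
absenteeism_cost <- function(inpatient_days, outpatient_hours,
                             wages = wage_inputs(), age,
                             retirement_age = 65) {
  if (any(c(inpatient_days, outpatient_hours) < 0)) {
    stop("utilization counts must be nonnegative", call. = FALSE)
  }
  ifelse(age >= retirement_age, 0,
         inpatient_days * wages$daily_wage +
           outpatient_hours * wages$hourly_wage)
}

#' Per-employee training cost in 2008 KRW
#'
#' Carries the per-employee training expenditure (USD, year 2000) to 2008
#' with the consumer price index and converts at the configured exchange
#' rate.
#'
#' @param config A `stroke_config`.
#' @return Training cost, thousand KRW.
#' @export
training_cost_krw <- function(config = stroke_config()) {
  config$training_cost_usd_2000 * (config$cpi_2008_base_2000 / 100) *
    config$exchange_rate_krw_per_usd / 1000
}

#' Premature-death productivity cost, friction-cost valuation
#'
#' Values a death before retirement as the wage over the friction period
#' (the time needed to replace a worker) plus the employer's per-employee
#' training cost; zero at or after retirement.
#'
#' @param gender `"male"` or `"female"`.
#' @param age_at_death Age at death in years.
#' @param wage_table A `wage_table` of annual wages, thousand KRW.
#' @param config A `stroke_config` (friction period and training-cost
#'   constants).
#' @return Friction-cost value of the death, thousand KRW.
#' @export
friction_premature_cost <- function(gender, age_at_death, wage_table,
                                    config = stroke_config()) {
  if (age_at_death >= config$retirement_age) return(0)
  config$friction_period_years * wage_at_age(wage_table, gender, age_at_death) +
    training_cost_krw(config)
}
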