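#' Run a gender x onset-age cohort through the Markov model
#'
#' Simulates the three-state natural history ('post primary stroke event',
#' 'alive post stroke', 'dead') with yearly cycles. The whole cohort
#' starts in 'post primary stroke event'; in cycle 1 the 12-month case
#' fatality `1 - first_year_survival` of the onset band is applied
#' directly as a probability (it is already a one-year proportion), and
#' survivors move to 'alive post stroke'. Every later cycle applies the
#' attained-age transition set (non-fatal recurrence, fatal recurrence,
#' non-stroke death, stay), with band parameters switching as the cohort
#' ages. The cohort is closed at `terminal_age`: anyone alive after the
#' cycle ending there is counted as dying in the following year with no
#' further costs.
#'
#' Expected costs per cycle: cycle 1 charges the first-year cost to
#' survivors and the fatal-stroke cost plus the premature-death cost of
#' the onset band to decedents. Later cycles charge the subsequent-year
#' cost to those staying alive without recurrence, the first-year cost to
#' non-fatal recurrences (subsequent-year costs resume afterwards), and
#' the fatal-stroke cost plus the premature-death cost of the attained-age
#' band to fatal recurrences. Non-stroke deaths incur no stroke cost.
#' Under `productivity_mode = "friction"` the premature-death component is
#' replaced by the friction-cost value ([friction_premature_cost()]),
#' which requires a wage table. No discounting is applied.
#'
#' @param gender `"male"` or `"female"`.
#' @param onset_age One of the modelled onset ages 45, 55, 65, 75, 85.
#' @param epi A validated `epi_table`.
#' @param cost A validated `cost_table` (thousand KRW).
#' @param config A `stroke_config`.
#' @param wage_table A `wage_table`; required for friction mode only.
#' @return A `cohort_trace` data frame with one row per cycle: attained
#'   age and band, the fraction entering the cycle alive, within-cycle
#'   event fractions, end-of-cycle `alive`/`dead` occupancy, and the
#'   cycle's expected `cost_medical` and `cost_premature` (thousand KRW
#'   per incident case).
#' @export
run_cohort <- function(gender, onset_age, epi, cost,
                       config = stroke_config(), wage_table = NULL) {
  if (!onset_age %in% stroke_bands()) {
    stop("onset_age must be one of ", paste(stroke_bands(), collapse = ", "),
         call. = FALSE)
  }
  friction <- config$productivity_mode == "friction"
  if (friction && is.null(wage_table)) {
    stop("friction mode requires a wage_table", call. = FALSE)
  }
  premature_unit <- function(age) {
    if (friction) {
      friction_premature_cost(gender, age, wage_table, config)
    } else {
      cost_row(cost, gender, band_of_age(age))$cost_premature_death
    }
  }

  n_cycles <- config$terminal_age - onset_age + 1L
  ages <- onset_age + seq_len(n_cycles) - 1L
  tr <- data.frame(
    cycle = seq_len(n_cycles),
    age = ages,
    band = band_of_age(ages),
    entering_alive = NA_real_,
    frac_nonfatal_recurrence = 0,
    frac_fatal_recurrence = 0,
    frac_nonstroke_death = 0,
    frac_stay = 0,
    alive = NA_real_,
    dead = NA_real_,
    cost_medical = NA_real_,
    cost_premature = NA_real_
  )

  s1 <- epi_row(epi, gender, onset_age)$first_year_survival
  c1 <- cost_row(cost, gender, onset_age)
  tr$entering_alive[1] <- 1
  tr$frac_stay[1] <- s1                      # first-year survivors
  tr$alive[1] <- s1
  tr$dead[1] <- 1 - s1
  tr$cost_medical[1] <- s1 * c1$cost_first_year + (1 - s1) * c1$cost_fatal
  tr$cost_premature[1] <- (1 - s1) * premature_unit(onset_age)

  for (k in seq_len(n_cycles)[-1]) {
    ts <- build_transition_set(gender, ages[k], epi, config)
    cb <- cost_row(cost, gender, ts$band)
    enter <- tr$alive[k - 1]
    nfr <- enter * ts$p_nonfatal_recurrence
    fr <- enter * ts$p_fatal_recurrence
    d <- enter * ts$p_nonstroke_death
    stay <- enter * ts$p_stay
    tr$entering_alive[k] <- enter
    tr$frac_nonfatal_recurrence[k] <- nfr
    tr$frac_fatal_recurrence[k] <- fr
    tr$frac_nonstroke_death[k] <- d
    tr$frac_stay[k] <- stay
    tr$alive[k] <- stay + nfr
    tr$dead[k] <- tr$dead[k - 1] + fr + d
    tr$cost_medical[k] <- nfr * cb$cost_first_year + fr * cb$cost_fatal +
      stay * cb$cost_subsequent_year
    tr$cost_premature[k] <- fr * premature_unit(ages[k])
  }

  structure(tr, class = c("cohort_trace", "data.frame"),
            gender = gender, onset_age = onset_age,
            productivity_mode = config$productivity_mode)
}

#' Post-stroke life expectancy from a cohort trace
#'
#' Life-years attach to the 'alive post stroke' state: each cycle spent
#' there (cycles 2 onwards, transitions at cycle start) credits one year
#' to the fraction still alive at the end of the cycle. The acute first
#' cycle is spent in 'post primary stroke event' and carries no life-year
#' reward; decedents contribute nothing in their cycle of death. See the
#' methods vignette for the rationale for this crediting convention.
#'
#' @param trace A `cohort_trace`.
#' @return Expected remaining life-years per incident case.
#' @export
life_expectancy <- function(trace) {
  sum(trace$alive[trace$cycle >= 2])
}

#' Years of life lost and relative reduction
#'
#' @param le_post_stroke Modelled post-stroke life expectancy (years).
#' @param le_general Age- and gender-matched general-population remaining
#'   life expectancy (years, `> 0`).
#' @return List with `yll` (years) and `reduction_pct`
#'   (`100 * yll / le_general`).
#' @export
years_of_life_lost <- function(le_post_stroke, le_general) {
  if (any(le_general <= 0)) {
    stop("general-population life expectancy must be positive", call. = FALSE)
  }
  yll <- le_general - le_post_stroke
  list(yll = yll, reduction_pct = 100 * yll / le_general)
}

#' Expected lifetime cost from a cohort trace
#'
#' Sums the per-cycle expected costs accumulated by [run_cohort()]; the
#' lifetime cost is the sum over all cycles, with no discounting.
#'
#' @param trace A `cohort_trace`.
#' @return A `lifetime_cost` list with `total`, `excl_premature` and
#'   `premature` (thousand KRW per incident case);
#'   `total = excl_premature + premature` exactly.
#' @export
expected_lifetime_cost <- function(trace) {
  excl <- sum(trace$cost_medical)
  prem <- sum(trace$cost_premature)
  structure(list(total = excl + prem, excl_premature = excl,
                 premature = prem),
            class = "lifetime_cost")
}

#' Lifetime results for all modelled cohorts
#'
#' Runs every gender x onset-age cohort and assembles post-stroke life
#' expectancy, years of life lost, the relative reduction in life
#' expectancy, and expected lifetime costs with and without
#' premature-death productivity costs.
#'
#' @param epi A validated `epi_table`.
#' @param cost A validated `cost_table`.
#' @param life A validated `life_table` of general-population life
#'   expectancies.
#' @param config A `stroke_config`.
#' @param wage_table Optional `wage_table` (needed for friction mode).
#' @return Data frame with one row per cohort: `gender`, `onset_age`,
#'   `le_general`, `le_model`, `yll`, `reduction_pct`, `cost_total`,
#'   `cost_excl_premature` (costs in thousand KRW).
#' @export
lifetime_table <- function(epi, cost, life, config = stroke_config(),
                           wage_table = NULL) {
  grid <- expand.grid(gender = c("male", "female"), onset_age = stroke_bands(),
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$gender, c("male", "female")), grid$onset_age), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$gender[i]; a <- grid$onset_age[i]
    trace <- run_cohort(g, a, epi, cost, config, wage_table)
    le <- life_expectancy(trace)
    le_gen <- life$life_expectancy[life$gender == g & life$age == a]
    yll <- years_of_life_lost(le, le_gen)
    lc <- expected_lifetime_cost(trace)
    data.frame(gender = g, onset_age = a, le_general = le_gen, le_model = le,
               yll = yll$yll, reduction_pct = yll$reduction_pct,
               cost_total = lc$total, cost_excl_premature = lc$excl_premature,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
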