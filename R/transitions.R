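#' Recurrent-stroke risk among people with prior stroke
#'
#' The published attack rate of acute stroke in the general population is
#' a prevalence-weighted mixture of first-ever incidence among people
#' without prior stroke and recurrence among people with prior stroke:
#' `attack_rate = p * R_s + (1 - p) * R_n`. Solving for the recurrent
#' risk gives `R_s = (attack_rate - (1 - p) * risk_new_onset) / p`.
#' All rates per 100,000 person-years.
#'
#' @param prevalence Fraction of the general population with prior stroke.
#' @param risk_new_onset First-ever stroke rate per 100,000 person-years
#'   among people without prior stroke.
#' @param attack_rate Acute stroke rate (first-ever + recurrent) per
#'   100,000 person-years in the general population.
#' @return Recurrent-stroke rate per 100,000 person-years. Vectorized.
#' @export
recurrent_risk <- function(prevalence, risk_new_onset, attack_rate) {
  if (any(prevalence <= 0)) {
    stop("prevalence must be positive: mixture decomposition is undefined",
         call. = FALSE)
  }
  num <- attack_rate - (1 - prevalence) * risk_new_onset
  if (any(num < -1e-9)) {
    stop("inconsistent inputs: attack_rate < (1 - prevalence) * risk_new_onset",
         call. = FALSE)
  }
  pmax(num, 0) / prevalence
}

#' Split recurrence into non-fatal and fatal components
#'
#' The one-year survival proportion after an acute stroke is used as the
#' non-fatal proportion of recurrent strokes.
#'
#' @param recurrent_risk Recurrent-stroke rate (any consistent scale).
#' @param p_nonfatal Proportion of recurrences that are non-fatal, in
#'   `[0, 1]`.
#' @return Data frame with columns `nonfatal` and `fatal`; the two sum to
#'   `recurrent_risk`.
#' @export
split_recurrence <- function(recurrent_risk, p_nonfatal) {
  if (any(p_nonfatal < 0) || any(p_nonfatal > 1)) {
    stop("p_nonfatal must lie in [0, 1]", call. = FALSE)
  }
  if (any(recurrent_risk < 0)) {
    stop("recurrent_risk must be nonnegative", call. = FALSE)
  }
  data.frame(nonfatal = recurrent_risk * p_nonfatal,
             fatal = recurrent_risk * (1 - p_nonfatal))
}

#' Non-stroke mortality in the post-stroke population
#'
#' Applies a standardized mortality ratio to general-population non-stroke
#' mortality: `D_s = D_t * SMR`.
#'
#' @param d_t Non-stroke death rate per 100,000 person-years in the
#'   general population.
#' @param smr Standardized mortality ratio (dimensionless, `> 0`).
#' @return Non-stroke death rate per 100,000 person-years among people
#'   with prior stroke. Vectorized.
#' @export
post_stroke_mortality <- function(d_t, smr) {
  if (any(d_t < 0)) stop("mortality rate must be nonnegative", call. = FALSE)
  if (any(smr <= 0)) stop("SMR must be positive", call. = FALSE)
  d_t * smr
}

#' Convert a rate to a per-cycle probability
#'
#' Constant-hazard conversion `p = 1 - exp(-r * t)` for a per-person-year
#' rate `r` and cycle length `t`. The result is bounded above by `r * t`.
#'
#' @param rate Per-person-year rate (per-100,000 values must be divided
#'   by 100,000 first).
#' @param cycle_length Cycle length in years (default 1).
#' @return Probability in `[0, 1)`. Vectorized.
#' @export
rate_to_probability <- function(rate, cycle_length = 1) {
  if (any(rate < 0)) stop("rate must be nonnegative", call. = FALSE)
  if (any(cycle_length <= 0)) {
    stop("cycle_length must be positive", call. = FALSE)
  }
  1 - exp(-rate * cycle_length)
}

#' Derived per-band risks
#'
#' Applies the mixture decomposition, the non-fatal/fatal split and the
#' standardized-mortality adjustment to every gender x band row of an
#' epidemiologic table.
#'
#' @param epi A validated `epi_table`.
#' @param config A `stroke_config`.
#' @return Data frame with per-100,000 columns `recurrent_risk`,
#'   `recurrent_nonfatal_risk`, `recurrent_fatal_risk`,
#'   `nonstroke_mortality` alongside `gender` and `band`.
#' @export
derive_risks <- function(epi, config = stroke_config()) {
  rs <- recurrent_risk(epi$prevalence, epi$risk_new_onset, epi$attack_rate)
  sp <- split_recurrence(rs, epi$first_year_survival)
  smr <- ifelse(epi$gender == "male", config$smr_male, config$smr_female)
  data.frame(
    gender = epi$gender,
    band = epi$band,
    recurrent_risk = rs,
    recurrent_nonfatal_risk = sp$nonfatal,
    recurrent_fatal_risk = sp$fatal,
    nonstroke_mortality = post_stroke_mortality(
      epi$nonstroke_mortality_general, smr),
    stringsAsFactors = FALSE
  )
}

#' Per-cycle transition probabilities at an attained age
#'
#' Looks up the band containing the attained age, derives the recurrent
#' and mortality risks, converts them to per-cycle probabilities with
#' [rate_to_probability()], and takes the stay-alive probability as the
#' complement of the three exits. If the three exit probabilities were to
#' exceed one, they are renormalized to sum to one and the stay
#' probability floored at zero.
#'
#' @param gender `"male"` or `"female"`.
#' @param attained_age Attained age in years, within
#'   `[45, terminal_age]`.
#' @param epi A validated `epi_table`.
#' @param config A `stroke_config`.
#' @return A `transition_set`: list with `p_nonfatal_recurrence`,
#'   `p_fatal_recurrence`, `p_nonstroke_death`, `p_stay` (the four sum to
#'   one), and the `gender`, `attained_age`, `band` used.
#' @export
build_transition_set <- function(gender, attained_age, epi,
                                 config = stroke_config()) {
  if (attained_age < 45 || attained_age > config$terminal_age) {
    stop("attained_age must lie in [45, terminal_age]", call. = FALSE)
  }
  band <- band_of_age(attained_age)
  row <- epi_row(epi, gender, band)
  rs <- recurrent_risk(row$prevalence, row$risk_new_onset, row$attack_rate)
  sp <- split_recurrence(rs, row$first_year_survival)
  ds <- post_stroke_mortality(row$nonstroke_mortality_general,
                              smr_for(config, gender))
  t <- config$cycle_length_years
  p_nfr <- rate_to_probability(sp$nonfatal / 1e5, t)
  p_fr <- rate_to_probability(sp$fatal / 1e5, t)
  p_d <- rate_to_probability(ds / 1e5, t)
  exits <- p_nfr + p_fr + p_d
  if (exits > 1) {
    p_nfr <- p_nfr / exits
    p_fr <- p_fr / exits
    p_d <- p_d / exits
    exits <- 1
  }
  structure(list(
    p_nonfatal_recurrence = p_nfr,
    p_fatal_recurrence = p_fr,
    p_nonstroke_death = p_d,
    p_stay = 1 - exits,
    gender = gender,
    attained_age = attained_age,
    band = band
  ), class = "transition_set")
}

#' Transition probabilities for every gender x band
#'
#' @param epi A validated `epi_table`.
#' @param config A `stroke_config`.
#' @return Data frame with one row per gender x band and the four
#'   per-cycle probabilities.
#' @export
transition_table <- function(epi, config = stroke_config()) {
  rows <- lapply(seq_len(nrow(epi)), function(i) {
    ts <- build_transition_set(epi$gender[i], epi$band[i], epi, config)
    data.frame(gender = ts$gender, band = ts$band,
               p_nonfatal_recurrence = ts$p_nonfatal_recurrence,
               p_fatal_recurrence = ts$p_fatal_recurrence,
               p_nonstroke_death = ts$p_nonstroke_death,
               p_stay = ts$p_stay,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
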