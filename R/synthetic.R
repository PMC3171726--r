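#' Generate an internally consistent synthetic scenario
#'
#' Draws a full set of model inputs — epidemiologic table, cost table,
#' general-population life table and wage table — from plausible ranges
#' (prevalence 0.1-10%, per-100,000 rates in realistic spans, one-year
#' survival 0.2-0.95, premature-death costs up to 600,000 thousand KRW),
#' with the structural constraints built in: the attack rate is
#' constructed as the prevalence-weighted mixture of first-ever and
#' recurrent risks (so the mixture decomposition recovers the true
#' recurrent risk exactly), mortality and prevalence increase with age,
#' and life expectancy decreases with age. Every generated table passes
#' the package validators. Tables supplied through the `...` overrides
#' are used as given, so a scenario can be pinned to the bundled national
#' tables.
#'
#' @param seed Integer seed; the same seed reproduces the same scenario.
#' @param epi,cost,life,wage Optional pre-built tables overriding the
#'   generated ones (validated on the way in).
#' @return A `synthetic_scenario` list with elements `epi`, `cost`,
#'   `life`, `wage`, `config`, `seed`, and `truth` (the recurrent risks
#'   the epi table was built from, `NULL` when `epi` is supplied).
#' @export
generate_scenario <- function(seed, epi = NULL, cost = NULL, life = NULL,
                              wage = NULL) {
  set.seed(seed)
  bands <- stroke_bands()
  truth <- NULL

  if (is.null(epi)) {
    rows <- lapply(c("male", "female"), function(g) {
      p <- sort(stats::runif(5, 0.001, 0.10))
      rn <- sort(stats::runif(5, 50, 3000))
      rs <- rn + stats::runif(5, 500, 17000)
      surv <- sort(stats::runif(5, 0.2, 0.95), decreasing = TRUE)
      dt <- sort(stats::runif(5, 100, 20000))
      data.frame(
        gender = g, band = bands, prevalence = p, risk_new_onset = rn,
        incident_cases = sample.int(20000, 5),
        attack_rate = p * rs + (1 - p) * rn,
        first_year_survival = surv, nonstroke_mortality_general = dt,
        true_recurrent_risk = rs, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    truth <- df[, c("gender", "band", "true_recurrent_risk")]
    df$true_recurrent_risk <- NULL
    epi <- validate_epi_table(df)
  } else {
    epi <- validate_epi_table(as.data.frame(epi))
  }

  if (is.null(cost)) {
    rows <- lapply(c("male", "female"), function(g) {
      c1 <- stats::runif(5, 4000, 10000)
      data.frame(
        gender = g, band = bands,
        cost_first_year = c1,
        cost_subsequent_year = stats::runif(5, 400, 2500),
        cost_fatal = stats::runif(5, 5000, 13000),
        cost_premature_death = c(stats::runif(2, 10000, 600000), 0, 0, 0),
        stringsAsFactors = FALSE)
    })
    cost <- validate_cost_table(do.call(rbind, rows))
  } else {
    cost <- validate_cost_table(as.data.frame(cost))
  }

  if (is.null(life)) {
    rows <- lapply(c("male", "female"), function(g) {
      le45 <- stats::runif(1, 28, 40)
      drops <- stats::runif(4, 3, 8)
      le <- le45 - cumsum(c(0, drops))
      le <- pmax(le, seq(12, 2, length.out = 5))   # keep old-age LE positive
      le <- rev(cummax(rev(le + seq(0.4, 0, length.out = 5))))
      data.frame(gender = g, age = bands,
                 life_expectancy = le - seq(0, 0.4, length.out = 5) * 0,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    # enforce strict decrease
    for (g in c("male", "female")) {
      le <- df$life_expectancy[df$gender == g]
      for (i in 2:5) le[i] <- min(le[i], le[i - 1] - 0.5)
      df$life_expectancy[df$gender == g] <- le
    }
    life <- validate_life_table(df)
  } else {
    life <- validate_life_table(as.data.frame(life))
  }

  if (is.null(wage)) {
    rows <- lapply(c("male", "female"), function(g) {
      data.frame(gender = g, band = bands,
                 annual_wage = c(stats::runif(2, 5000, 60000), 0, 0, 0),
                 stringsAsFactors = FALSE)
    })
    wage <- validate_wage_table(do.call(rbind, rows))
  } else {
    wage <- validate_wage_table(as.data.frame(wage))
  }

  structure(list(epi = epi, cost = cost, life = life, wage = wage,
                 config = stroke_config(), seed = seed, truth = truth),
            class = "synthetic_scenario")
}

#' Monte-Carlo microsimulation oracle
#'
#' Simulates `n` independent individual life histories through the same
#' per-cycle transition sets used by the cohort engine (the transition
#' derivation is shared; the expectation accumulation is not) and
#' estimates mean life-years and mean lifetime cost with Monte-Carlo
#' standard errors. Life-years and costs follow the cohort engine's
#' conventions: the acute first cycle carries costs but no life-year
#' credit, each completed post-acute cycle alive credits one year, and
#' costs are charged per event/state exactly as in [run_cohort()].
#'
#' @param gender `"male"` or `"female"`.
#' @param onset_age One of the modelled onset ages.
#' @param epi,cost Validated input tables.
#' @param config A `stroke_config`.
#' @param n Number of simulated individuals (`>= 1000`).
#' @param seed Integer seed.
#' @param wage_table Optional `wage_table` (friction mode).
#' @return List with `mean_life_years`, `se_life_years`, `mean_cost`,
#'   `se_cost`, `n`.
#' @export
microsim_oracle <- function(gender, onset_age, epi, cost,
                            config = stroke_config(), n = 10000, seed = 1,
                            wage_table = NULL) {
  if (n < 1000) stop("n must be at least 1,000", call. = FALSE)
  set.seed(seed)
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

  s1 <- epi_row(epi, gender, onset_age)$first_year_survival
  c1 <- cost_row(cost, gender, onset_age)
  total_cost <- numeric(n)
  years <- numeric(n)
  u <- stats::runif(n)
  alive <- u < s1
  total_cost[alive] <- c1$cost_first_year
  total_cost[!alive] <- c1$cost_fatal + premature_unit(onset_age)

  for (k in seq_len(n_cycles)[-1]) {
    idx <- which(alive)
    if (!length(idx)) break
    ts <- build_transition_set(gender, ages[k], epi, config)
    cb <- cost_row(cost, gender, ts$band)
    cp <- premature_unit(ages[k])
    u <- stats::runif(length(idx))
    cuts <- cumsum(c(ts$p_nonfatal_recurrence, ts$p_fatal_recurrence,
                     ts$p_nonstroke_death))
    cat <- findInterval(u, cuts)   # 0 nfr, 1 fatal rec, 2 nonstroke death, 3 stay
    nfr <- idx[cat == 0L]
    fr <- idx[cat == 1L]
    d <- idx[cat == 2L]
    stay <- idx[cat == 3L]
    total_cost[nfr] <- total_cost[nfr] + cb$cost_first_year
    total_cost[fr] <- total_cost[fr] + cb$cost_fatal + cp
    total_cost[stay] <- total_cost[stay] + cb$cost_subsequent_year
    years[c(nfr, stay)] <- years[c(nfr, stay)] + 1
    alive[c(fr, d)] <- FALSE
  }

  list(mean_life_years = mean(years),
       se_life_years = stats::sd(years) / sqrt(n),
       mean_cost = mean(total_cost),
       se_cost = stats::sd(total_cost) / sqrt(n),
       n = n)
}

.stroke_codes <- c("I60", "I61", "I62", "I63", "I64")

#' Generate synthetic stroke claim records
#'
#' Produces individual-level claim-like records for testing incident-case
#' ascertainment: stroke claims (ICD-10 I60-I64, inpatient or outpatient)
#' scattered over the years around an index year, with some people
#' carrying claims inside the washout window, some with only older
#' history, repeat claims, and death dates at varying intervals after
#' their first index-year claim.
#'
#' @param n_people Number of people to simulate.
#' @param index_year Calendar year of case ascertainment.
#' @param seed Integer seed.
#' @return Data frame of claims: `person_id`, `date` (`Date`), `code`,
#'   `setting`, `death_date` (`Date` or `NA`), one row per claim.
#' @export
generate_claims <- function(n_people = 1000, index_year = 2002, seed = 1) {
  set.seed(seed)
  year_start <- as.Date(paste0(index_year, "-01-01"))
  recs <- vector("list", n_people)
  for (i in seq_len(n_people)) {
    dates <- as.Date(character(0))
    # older history outside the washout window
    if (stats::runif(1) < 0.20) {
      dates <- c(dates, year_start - sample(366:1095, sample(1:2, 1)))
    }
    # claims inside the one-year washout window
    if (stats::runif(1) < 0.15) {
      dates <- c(dates, year_start - sample(1:365, sample(1:2, 1)))
    }
    # index-year claims
    has_index <- stats::runif(1) < 0.70
    if (has_index) {
      first <- year_start + sample(0:364, 1)
      dates <- c(dates, first,
                 if (stats::runif(1) < 0.5) first + sample(1:300, sample(1:3, 1)))
    }
    if (!length(dates)) next
    death <- as.Date(NA)
    if (has_index && stats::runif(1) < 0.30) {
      death <- min(dates[dates >= year_start]) + sample(10:700, 1)
      dates <- dates[dates <= death]
    }
    recs[[i]] <- data.frame(
      person_id = i,
      date = sort(unique(dates)),
      code = sample(.stroke_codes, length(unique(dates)), replace = TRUE),
      setting = sample(c("inpatient", "outpatient"), length(unique(dates)),
                       replace = TRUE),
      death_date = death,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Ascertain incident (first-ever) stroke cases from claims
#'
#' A person is an incident case if their first stroke claim of the index
#' year is preceded by no stroke claim during the washout window (the
#' `window_years` years before that claim, at 365 days per year). An
#' incident case is fatal if death occurred within 365 days of the index
#' event, non-fatal otherwise.
#'
#' @param claims Data frame of claims as from [generate_claims()]
#'   (columns `person_id`, `date`, `death_date`; any code/setting
#'   columns are ignored for ascertainment).
#' @param index_year Calendar year of ascertainment.
#' @param window_years Washout window length in years (default 1).
#' @return Data frame with one row per incident case: `person_id`,
#'   `index_date`, `fatal`.
#' @export
ascertain_incident_cases <- function(claims, index_year, window_years = 1) {
  yr <- as.integer(format(claims$date, "%Y"))
  out <- lapply(split(seq_len(nrow(claims)), claims$person_id), function(ii) {
    dates <- claims$date[ii]
    in_year <- dates[yr[ii] == index_year]
    if (!length(in_year)) return(NULL)
    index <- min(in_year)
    window_lo <- index - 365L * window_years
    if (any(dates >= window_lo & dates < index)) return(NULL)
    death <- claims$death_date[ii][1]
    fatal <- !is.na(death) && as.numeric(death - index) <= 365
    data.frame(person_id = claims$person_id[ii][1], index_date = index,
               fatal = fatal, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(person_id = integer(0), index_date = as.Date(character(0)),
                      fatal = logical(0)))
  }
  out <- out[order(out$person_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
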