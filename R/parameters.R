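#' Modelled onset/age bands
#'
#' Lower bounds of the five 10-year age bands used throughout the model.
#' The last band (85) is open-ended.
#'
#' @return Integer vector `c(45, 55, 65, 75, 85)`.
#' @export
stroke_bands <- function() c(45L, 55L, 65L, 75L, 85L)

#' Age band containing an attained age
#'
#' Step function of attained age with breaks at 55, 65, 75 and 85
#' (no interpolation): band parameters switch as a cohort ages.
#'
#' @param age Attained age(s) in years, `>= 45`.
#' @return The band lower bound(s) containing `age`.
#' @export
band_of_age <- function(age) {
  if (any(age < 45)) stop("attained age below 45 is outside the modelled range")
  stroke_bands()[findInterval(age, stroke_bands())]
}

.genders <- c("male", "female")

stop_row <- function(table, gender, band, rule) {
  stop(sprintf("%s row (%s, %s): %s", table, gender, band, rule), call. = FALSE)
}

check_complete_keys <- function(df, table) {
  want <- expand.grid(gender = .genders, band = stroke_bands(),
                      stringsAsFactors = FALSE)
  key <- paste(df$gender, df$band)
  for (i in seq_len(nrow(want))) {
    k <- paste(want$gender[i], want$band[i])
    n <- sum(key == k)
    if (n == 0L) stop_row(table, want$gender[i], want$band[i], "missing row")
    if (n > 1L) stop_row(table, want$gender[i], want$band[i], "duplicate key")
  }
  bad <- !(df$gender %in% .genders) | !(df$band %in% stroke_bands())
  if (any(bad)) {
    stop_row(table, df$gender[bad][1], df$band[bad][1],
             "gender must be male/female and band one of 45/55/65/75/85")
  }
  invisible(df)
}

#' Validate an epidemiologic parameter table
#'
#' Checks completeness (each gender x band exactly once) and the row
#' invariants: prevalence and one-year survival are fractions, rates are
#' nonnegative, incident case counts are nonnegative integers, and the
#' attack rate is at least `(1 - prevalence) * risk_new_onset` so that the
#' derived recurrent risk is nonnegative.
#'
#' @param df Data frame with columns `gender`, `band`, `prevalence`,
#'   `risk_new_onset`, `incident_cases`, `attack_rate`,
#'   `first_year_survival`, `nonstroke_mortality_general` (per-100,000
#'   columns on the per-100,000 scale, proportions as fractions).
#' @return The validated table, classed `epi_table`, invisibly usable.
#' @export
validate_epi_table <- function(df) {
  need <- c("gender", "band", "prevalence", "risk_new_onset", "incident_cases",
            "attack_rate", "first_year_survival", "nonstroke_mortality_general")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("epi table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_complete_keys(df, "epi table")
  for (i in seq_len(nrow(df))) {
    g <- df$gender[i]; b <- df$band[i]
    if (!is.finite(df$prevalence[i]) || df$prevalence[i] <= 0 ||
        df$prevalence[i] >= 1) {
      stop_row("epi table", g, b, "prevalence must lie strictly in (0, 1)")
    }
    if (!is.finite(df$first_year_survival[i]) ||
        df$first_year_survival[i] <= 0 || df$first_year_survival[i] > 1) {
      stop_row("epi table", g, b, "first_year_survival must lie in (0, 1]")
    }
    rates <- c(df$risk_new_onset[i], df$attack_rate[i],
               df$nonstroke_mortality_general[i])
    if (any(!is.finite(rates)) || any(rates < 0)) {
      stop_row("epi table", g, b, "rates must be nonnegative")
    }
    if (df$incident_cases[i] < 0 ||
        df$incident_cases[i] != round(df$incident_cases[i])) {
      stop_row("epi table", g, b, "incident_cases must be a nonnegative integer")
    }
    if (df$attack_rate[i] <
        (1 - df$prevalence[i]) * df$risk_new_onset[i] - 1e-9) {
      stop_row("epi table", g, b,
               "attack_rate must be >= (1 - prevalence) * risk_new_onset")
    }
  }
  df <- df[order(match(df$gender, .genders), df$band), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("epi_table", "data.frame")
  df
}

#' Read an epidemiologic parameter table
#'
#' Reads a delimited-text table of gender x age-band epidemiologic
#' parameters: stroke prevalence, first-ever stroke incidence and acute
#' stroke attack rate (both per 100,000 person-years), incident case
#' counts, one-year survival after an acute stroke, and non-stroke
#' mortality in the general population (per 100,000 person-years).
#' Percent columns (`prevalence_pct`, `first_year_survival_pct`) are
#' converted to fractions at load; per-100,000 columns stay on their
#' printed scale. An optional `recurrent_risk_printed` column (published
#' recurrent-stroke risk) is carried along for cross-checking.
#'
#' @param path Path to a CSV file with a header row; gender coded
#'   `male`/`female`, band by its lower bound.
#' @return A validated `epi_table` data frame.
#' @seealso [korea_epi_table()] for the bundled national table.
#' @export
load_epi_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gender", "band", "prevalence_pct", "risk_new_onset",
            "incident_cases", "attack_rate", "first_year_survival_pct",
            "nonstroke_mortality_general")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("epi table file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(
    gender = raw$gender,
    band = as.integer(raw$band),
    prevalence = raw$prevalence_pct / 100,
    risk_new_onset = raw$risk_new_onset,
    incident_cases = raw$incident_cases,
    attack_rate = raw$attack_rate,
    first_year_survival = raw$first_year_survival_pct / 100,
    nonstroke_mortality_general = raw$nonstroke_mortality_general,
    stringsAsFactors = FALSE
  )
  if ("recurrent_risk_printed" %in% names(raw)) {
    df$recurrent_risk_printed <- raw$recurrent_risk_printed
  }
  validate_epi_table(df)
}

#' Write an epidemiologic parameter table
#'
#' Inverse of [load_epi_table()]: writes the table back to CSV on the
#' printed scales (percent columns, per-100,000 rates) so that a
#' write-then-read round trip reproduces every field exactly.
#'
#' @param epi A validated `epi_table`.
#' @param path Output CSV path.
#' @export
write_epi_table <- function(epi, path) {
  out <- data.frame(
    gender = epi$gender,
    band = epi$band,
    prevalence_pct = epi$prevalence * 100,
    risk_new_onset = epi$risk_new_onset,
    incident_cases = epi$incident_cases,
    attack_rate = epi$attack_rate,
    stringsAsFactors = FALSE
  )
  if ("recurrent_risk_printed" %in% names(epi)) {
    out$recurrent_risk_printed <- epi$recurrent_risk_printed
  }
  out$first_year_survival_pct <- epi$first_year_survival * 100
  out$nonstroke_mortality_general <- epi$nonstroke_mortality_general
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a per-person annual cost table
#'
#' Costs are in thousand KRW. The premature-death (human-capital) cost
#' must be zero for onset bands at or above retirement (65), where
#' productivity losses are not valued.
#'
#' @param df Data frame with columns `gender`, `band`, `cost_first_year`,
#'   `cost_subsequent_year`, `cost_fatal`, `cost_premature_death`.
#' @return The validated table, classed `cost_table`.
#' @export
validate_cost_table <- function(df) {
  need <- c("gender", "band", "cost_first_year", "cost_subsequent_year",
            "cost_fatal", "cost_premature_death")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cost table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_complete_keys(df, "cost table")
  for (i in seq_len(nrow(df))) {
    g <- df$gender[i]; b <- df$band[i]
    costs <- c(df$cost_first_year[i], df$cost_subsequent_year[i],
               df$cost_fatal[i], df$cost_premature_death[i])
    if (any(!is.finite(costs)) || any(costs < 0)) {
      stop_row("cost table", g, b, "costs must be nonnegative")
    }
    if (b >= 65 && df$cost_premature_death[i] != 0) {
      stop_row("cost table", g, b,
               "premature-death cost must be zero at/after retirement bands")
    }
  }
  df <- df[order(match(df$gender, .genders), df$band), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cost_table", "data.frame")
  df
}

#' Read a per-person annual cost table
#'
#' Reads first-year, subsequent-year and fatal-stroke costs per person,
#' and the premature-death productivity cost under human-capital
#' valuation, by gender and onset band, all in thousand KRW. A blank
#' premature-death cell (bands at/after retirement) is stored as 0.
#'
#' @param path Path to a CSV file.
#' @return A validated `cost_table` data frame.
#' @export
load_cost_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("cost_premature_death" %in% names(raw)) {
    raw$cost_premature_death[is.na(raw$cost_premature_death)] <- 0
  } else {
    raw$cost_premature_death <- 0
  }
  raw$band <- as.integer(raw$band)
  validate_cost_table(raw)
}

#' Write a per-person annual cost table
#'
#' @param cost A validated `cost_table`.
#' @param path Output CSV path.
#' @export
write_cost_table <- function(cost, path) {
  out <- as.data.frame(cost)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a general-population life-expectancy table
#'
#' Remaining life expectancy at the exact modelled onset ages must
#' strictly decrease with age within gender.
#'
#' @param df Data frame with columns `gender`, `age`, `life_expectancy`.
#' @return The validated table, classed `life_table`.
#' @export
validate_life_table <- function(df) {
  need <- c("gender", "age", "life_expectancy")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("life table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  names(df)[names(df) == "age"] <- "band"
  check_complete_keys(df, "life table")
  names(df)[names(df) == "band"] <- "age"
  for (g in .genders) {
    le <- df$life_expectancy[df$gender == g][order(df$age[df$gender == g])]
    if (any(!is.finite(le)) || any(le <= 0)) {
      stop_row("life table", g, "*", "life expectancy must be positive")
    }
    if (any(diff(le) >= 0)) {
      stop_row("life table", g, "*",
               "life expectancy must strictly decrease with age")
    }
  }
  df <- df[order(match(df$gender, .genders), df$age), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("life_table", "data.frame")
  df
}

#' Read a general-population life-expectancy table
#'
#' @param path Path to a CSV file with columns `gender`, `age`,
#'   `life_expectancy` (years remaining at the exact onset ages).
#' @return A validated `life_table` data frame.
#' @export
load_life_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$age <- as.integer(raw$age)
  validate_life_table(raw)
}

#' Write a general-population life-expectancy table
#'
#' @param life A validated `life_table`.
#' @param path Output CSV path.
#' @export
write_life_table <- function(life, path) {
  utils::write.csv(as.data.frame(life), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a gender x age-band annual wage table
#'
#' @param df Data frame with columns `gender`, `band`, `annual_wage`
#'   (thousand KRW per year).
#' @return The validated table, classed `wage_table`.
#' @export
validate_wage_table <- function(df) {
  need <- c("gender", "band", "annual_wage")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("wage table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_complete_keys(df, "wage table")
  if (any(!is.finite(df$annual_wage)) || any(df$annual_wage < 0)) {
    stop("wage table: annual wages must be nonnegative", call. = FALSE)
  }
  df <- df[order(match(df$gender, .genders), df$band), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("wage_table", "data.frame")
  df
}

#' Read a gender x age-band annual wage table
#'
#' @param path Path to a CSV file with columns `gender`, `band`,
#'   `annual_wage` (thousand KRW per year).
#' @return A validated `wage_table` data frame.
#' @export
load_wage_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$band <- as.integer(raw$band)
  validate_wage_table(raw)
}

#' Write a gender x age-band annual wage table
#'
#' @param wages A validated `wage_table`.
#' @param path Output CSV path.
#' @export
write_wage_table <- function(wages, path) {
  utils::write.csv(as.data.frame(wages), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "strokecoi")
  if (p == "") stop("bundled fixture not found: ", file, call. = FALSE)
  p
}

#' Bundled Korean national epidemiologic parameter table
#'
#' Gender x 10-year-band stroke prevalence, first-ever incidence, attack
#' rate, 2004 incident case counts, one-year survival and general-population
#' non-stroke mortality, as published for the Korean population.
#'
#' @return A validated `epi_table`.
#' @export
korea_epi_table <- function() load_epi_table(fixture_path("epi_params.csv"))

#' Bundled Korean per-person annual cost table
#'
#' Published average per-person annual costs of stroke (thousand KRW,
#' 2008 values) by gender and onset age: first-year and subsequent-year
#' costs of non-fatal stroke, the cost of fatal stroke, and the
#' human-capital premature-death cost (zero at/after retirement).
#'
#' @return A validated `cost_table`.
#' @export
korea_cost_table <- function() load_cost_table(fixture_path("cost_params.csv"))

#' Bundled Korean general-population life expectancies
#'
#' @return A validated `life_table` of remaining life expectancy at the
#'   modelled onset ages.
#' @export
korea_life_table <- function() {
  load_life_table(fixture_path("genpop_life_expectancy.csv"))
}

#' Bundled synthetic annual wage table
#'
#' A synthetic gender x band wage schedule (thousand KRW/year) constructed
#' so that the human-capital premature-death rule reproduces the bundled
#' cost table's premature-death entries exactly; the underlying national
#' wage statistics are not published in the source tables. Intended for
#' testing and for friction-cost calculations; labelled synthetic.
#'
#' @return A validated `wage_table`.
#' @export
synthetic_wage_table <- function() {
  load_wage_table(fixture_path("wage_table_synthetic.csv"))
}

#' Model configuration
#'
#' Assembles and validates the model's global settings: cycle length,
#' terminal age (cohorts are closed at this age), retirement age (no
#' productivity losses beyond it), standardized mortality ratios applied
#' to general-population non-stroke mortality, the productivity valuation
#' mode, and the friction-cost constants (friction period, per-employee
#' training cost in 2000 USD, consumer price index used to carry it to
#' 2008, and the KRW/USD exchange rate).
#'
#' @param cycle_length_years Cycle length in years (default 1).
#' @param terminal_age Age at which cohorts are closed (default 99).
#' @param retirement_age Retirement age (default 65).
#' @param smr_male,smr_female Standardized mortality ratios for non-stroke
#'   death among people with prior stroke (defaults 1.914 and 2.295).
#' @param productivity_mode `"human_capital"` or `"friction"`.
#' @param friction_period_years Friction period in years (default 0.5).
#' @param training_cost_usd_2000 Per-employee training cost, USD in 2000
#'   (default 362).
#' @param cpi_2008_base_2000 Consumer price index in 2008 with 2000 = 100
#'   (default 129.3).
#' @param exchange_rate_krw_per_usd KRW per USD (default 1200).
#' @return A classed `stroke_config` list.
#' @export
stroke_config <- function(cycle_length_years = 1,
                          terminal_age = 99,
                          retirement_age = 65,
                          smr_male = 1.914,
                          smr_female = 2.295,
                          productivity_mode = c("human_capital", "friction"),
                          friction_period_years = 0.5,
                          training_cost_usd_2000 = 362,
                          cpi_2008_base_2000 = 129.3,
                          exchange_rate_krw_per_usd = 1200) {
  productivity_mode <- match.arg(productivity_mode)
  if (cycle_length_years <= 0) {
    stop("cycle_length_years must be positive", call. = FALSE)
  }
  if (terminal_age <= max(stroke_bands())) {
    stop("terminal_age must exceed all onset ages", call. = FALSE)
  }
  if (smr_male <= 0 || smr_female <= 0) {
    stop("standardized mortality ratios must be positive", call. = FALSE)
  }
  structure(list(
    cycle_length_years = cycle_length_years,
    terminal_age = terminal_age,
    retirement_age = retirement_age,
    smr_male = smr_male,
    smr_female = smr_female,
    productivity_mode = productivity_mode,
    friction_period_years = friction_period_years,
    training_cost_usd_2000 = training_cost_usd_2000,
    cpi_2008_base_2000 = cpi_2008_base_2000,
    exchange_rate_krw_per_usd = exchange_rate_krw_per_usd
  ), class = "stroke_config")
}

#' Read a model configuration from a YAML file
#'
#' Fields absent from the file keep their [stroke_config()] defaults.
#'
#' @param path Path to a flat key-value YAML file.
#' @return A classed `stroke_config` list.
#' @export
read_stroke_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(stroke_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(stroke_config, vals)
}

smr_for <- function(config, gender) {
  switch(gender, male = config$smr_male, female = config$smr_female,
         stop("gender must be 'male' or 'female'", call. = FALSE))
}

epi_row <- function(epi, gender, band) {
  i <- which(epi$gender == gender & epi$band == band)
  if (length(i) != 1L) {
    stop(sprintf("no epi row for (%s, %s)", gender, band), call. = FALSE)
  }
  epi[i, , drop = FALSE]
}

cost_row <- function(cost, gender, band) {
  i <- which(cost$gender == gender & cost$band == band)
  if (length(i) != 1L) {
    stop(sprintf("no cost row for (%s, %s)", gender, band), call. = FALSE)
  }
  cost[i, , drop = FALSE]
}
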