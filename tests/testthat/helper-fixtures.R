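# Bundled national tables, loaded once per test run.
epi_fix <- korea_epi_table()
cost_fix <- korea_cost_table()
life_fix <- korea_life_table()
wage_fix <- synthetic_wage_table()
cfg_fix <- stroke_config()

# A degenerate scenario: nobody recurs and nobody dies (immortal cohort).
immortal_epi <- function() {
  df <- as.data.frame(epi_fix)
  df$risk_new_onset <- 0
  df$attack_rate <- 0
  df$nonstroke_mortality_general <- 0
  df$first_year_survival <- 1
  validate_epi_table(df)
}

zero_cost_table <- function() {
  df <- as.data.frame(cost_fix)
  df$cost_first_year <- 0
  df$cost_subsequent_year <- 0
  df$cost_fatal <- 0
  df$cost_premature_death <- 0
  validate_cost_table(df)
}

# Independent brute-force incident-case ascertainment used as an oracle.
brute_force_ascertain <- function(claims, index_year, window_years = 1) {
  ids <- sort(unique(claims$person_id))
  rows <- list()
  for (id in ids) {
    sub <- claims[claims$person_id == id, ]
    sub <- sub[order(sub$date), ]
    index <- NA
    for (j in seq_len(nrow(sub))) {
      if (format(sub$date[j], "%Y") == as.character(index_year)) {
        index <- sub$date[j]
        break
      }
    }
    if (is.na(index)) next
    clean <- TRUE
    for (j in seq_len(nrow(sub))) {
      if (sub$date[j] < index && sub$date[j] >= index - 365 * window_years) {
        clean <- FALSE
      }
    }
    if (!clean) next
    death <- sub$death_date[1]
    fatal <- !is.na(death) && as.numeric(death - index) <= 365
    rows[[length(rows) + 1]] <- data.frame(person_id = id, index_date = index,
                                           fatal = fatal)
  }
  if (!length(rows)) {
    return(data.frame(person_id = integer(0),
                      index_date = as.Date(character(0)),
                      fatal = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
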