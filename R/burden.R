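#' National lifetime burden from incident counts and per-person costs
#'
#' Multiplies the incident case count of every gender x band by the
#' per-person lifetime cost of the band's onset age and aggregates to
#' age-group totals and shares (incidence shares and cost shares), both
#' per 10-year band and for the 45-64 working-age aggregate.
#'
#' @param epi A validated `epi_table` (incident case counts).
#' @param lifetime_costs Data frame with columns `gender`, `onset_age`,
#'   `cost_total` (thousand KRW per person), e.g. the output of
#'   [lifetime_table()].
#' @return A `burden_result` list: `by_cohort` (cells), `by_band`
#'   (cases, costs, incidence and cost shares in percent, pooled over
#'   gender), `total` (thousand KRW), and the 45-64 aggregates
#'   `incidence_share_45_64_pct`, `cost_share_45_64_pct`.
#' @export
national_burden <- function(epi, lifetime_costs) {
  need <- c("gender", "onset_age", "cost_total")
  miss <- setdiff(need, names(lifetime_costs))
  if (length(miss)) {
    stop("lifetime_costs is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  by_cohort <- merge(
    data.frame(gender = epi$gender, onset_age = epi$band,
               incident_cases = epi$incident_cases,
               stringsAsFactors = FALSE),
    lifetime_costs[, need], by = c("gender", "onset_age"))
  if (nrow(by_cohort) != nrow(epi)) {
    stop("lifetime_costs must cover every gender x band", call. = FALSE)
  }
  by_cohort$burden <- by_cohort$incident_cases * by_cohort$cost_total
  total <- sum(by_cohort$burden)

  bands <- stroke_bands()
  by_band <- data.frame(
    band = bands,
    incident_cases = vapply(bands, function(b) {
      sum(by_cohort$incident_cases[by_cohort$onset_age == b])
    }, numeric(1)),
    burden = vapply(bands, function(b) {
      sum(by_cohort$burden[by_cohort$onset_age == b])
    }, numeric(1))
  )
  all_cases <- sum(by_band$incident_cases)
  by_band$incidence_share_pct <- 100 * by_band$incident_cases / all_cases
  by_band$cost_share_pct <- 100 * by_band$burden / total

  young <- by_band$band %in% c(45, 55)
  structure(list(
    by_cohort = by_cohort,
    by_band = by_band,
    total = total,
    incidence_share_45_64_pct = sum(by_band$incidence_share_pct[young]),
    cost_share_45_64_pct = sum(by_band$cost_share_pct[young])
  ), class = "burden_result")
}

scale_cost_table <- function(cost, factor, include_premature) {
  out <- as.data.frame(cost)
  for (col in c("cost_first_year", "cost_subsequent_year", "cost_fatal")) {
    out[[col]] <- out[[col]] * factor
  }
  if (include_premature) {
    out$cost_premature_death <- out$cost_premature_death * factor
  }
  validate_cost_table(out)
}

#' One-way sensitivity analysis of per-person lifetime costs
#'
#' Reruns the full cohort pipeline under: the standardized mortality
#' ratios of both genders scaled by `1 +/- scale`; all unit costs scaled
#' by `1 +/- scale` (by default the premature-death cost is left at its
#' base value, since it is a valuation rather than a price — set
#' `scale_premature = TRUE` to scale it too); and the friction-cost
#' productivity valuation in place of the human-capital one.
#'
#' @param epi,cost,life Validated input tables.
#' @param config Base-case `stroke_config`.
#' @param wage_table A `wage_table`; required for the friction scenario.
#' @param scenarios Subset of `c("smr", "costs", "friction")`.
#' @param scale Relative perturbation (default 0.2 for +/-20%).
#' @param scale_premature Scale the premature-death cost along with the
#'   other unit costs (default `FALSE`).
#' @return Data frame with one row per cohort: base-case cost and, per
#'   scenario, the low/high recomputed lifetime costs (`smr_low`,
#'   `smr_high` ordered so that `low <= high`), `cost_low`, `cost_high`,
#'   and `friction` (thousand KRW).
#' @export
one_way_sensitivity <- function(epi, cost, life, config = stroke_config(),
                                wage_table = NULL,
                                scenarios = c("smr", "costs", "friction"),
                                scale = 0.2, scale_premature = FALSE) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  if ("friction" %in% scenarios && is.null(wage_table)) {
    stop("the friction scenario requires a wage_table", call. = FALSE)
  }
  base <- lifetime_table(epi, cost, life, config, wage_table)
  out <- base[, c("gender", "onset_age")]
  out$base <- base$cost_total

  config_with_smr <- function(f) {
    cfg <- config
    cfg$smr_male <- config$smr_male * f
    cfg$smr_female <- config$smr_female * f
    cfg
  }
  if ("smr" %in% scenarios) {
    lo <- lifetime_table(epi, cost, life, config_with_smr(1 - scale),
                         wage_table)$cost_total
    hi <- lifetime_table(epi, cost, life, config_with_smr(1 + scale),
                         wage_table)$cost_total
    out$smr_low <- pmin(lo, hi)
    out$smr_high <- pmax(lo, hi)
  }
  if ("costs" %in% scenarios) {
    lo <- lifetime_table(epi, scale_cost_table(cost, 1 - scale,
                                               scale_premature),
                         life, config, wage_table)$cost_total
    hi <- lifetime_table(epi, scale_cost_table(cost, 1 + scale,
                                               scale_premature),
                         life, config, wage_table)$cost_total
    out$cost_low <- pmin(lo, hi)
    out$cost_high <- pmax(lo, hi)
  }
  if ("friction" %in% scenarios) {
    cfg <- config
    cfg$productivity_mode <- "friction"
    out$friction <- lifetime_table(epi, cost, life, cfg,
                                   wage_table)$cost_total
  }
  out
}
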