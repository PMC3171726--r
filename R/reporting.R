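fmt_krw <- function(x) formatC(round(x), format = "d", big.mark = ",")

#' Render the years-of-life-lost report table
#'
#' Formats the cohort results as the published life-table layout: one row
#' per gender x onset age with general-population life expectancy,
#' modelled post-stroke life expectancy, years of life lost and the
#' percent reduction, rounded to two decimals. All rounding happens here;
#' upstream computation keeps full precision.
#'
#' @param results Output of [lifetime_table()] (all ten cohorts).
#' @return Data frame ready for printing/CSV export.
#' @export
render_life_table <- function(results) {
  if (is.null(results) || nrow(results) == 0) {
    stop("no cohort results to render", call. = FALSE)
  }
  data.frame(
    gender = results$gender,
    onset_age = results$onset_age,
    le_general = round(results$le_general, 2),
    le_post_stroke = round(results$le_model, 2),
    years_of_life_lost = round(results$yll, 2),
    reduction_pct = round(results$reduction_pct, 2)
  )
}

#' Render the lifetime-cost report table
#'
#' Formats per-person lifetime costs in the published layout: the
#' base-case cost with the premature-death-exclusive value in
#' parentheses, and (when a sensitivity analysis is supplied) the
#' low~high ranges for the SMR and unit-cost scenarios plus the
#' friction-cost column.
#'
#' @param results Output of [lifetime_table()].
#' @param sensitivity Optional output of [one_way_sensitivity()] aligned
#'   on `gender` and `onset_age`.
#' @return Data frame of formatted strings (thousand KRW).
#' @export
render_cost_table <- function(results, sensitivity = NULL) {
  if (is.null(results) || nrow(results) == 0) {
    stop("no cohort results to render", call. = FALSE)
  }
  out <- data.frame(
    gender = results$gender,
    onset_age = results$onset_age,
    base_case = sprintf("%s (%s)", fmt_krw(results$cost_total),
                        fmt_krw(results$cost_excl_premature)),
    stringsAsFactors = FALSE
  )
  if (!is.null(sensitivity)) {
    m <- match(paste(out$gender, out$onset_age),
               paste(sensitivity$gender, sensitivity$onset_age))
    if (anyNA(m)) stop("sensitivity results do not cover all cohorts",
                       call. = FALSE)
    s <- sensitivity[m, ]
    if (all(c("smr_low", "smr_high") %in% names(s))) {
      out$smr_pm20 <- sprintf("%s~%s", fmt_krw(s$smr_low), fmt_krw(s$smr_high))
    }
    if (all(c("cost_low", "cost_high") %in% names(s))) {
      out$cost_pm20 <- sprintf("%s~%s", fmt_krw(s$cost_low),
                               fmt_krw(s$cost_high))
    }
    if ("friction" %in% names(s)) {
      out$friction <- fmt_krw(s$friction)
    }
  }
  out
}
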