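#' Decision-analytic context for a health benefits package analysis
#'
#' Bundles the global parameters shared by every intervention in an evidence
#' base: the delivery horizon, the annual discount rate(s), the health
#' opportunity cost of spending, and the simulation settings.
#'
#' @param time_horizon_years Integer number of years the interventions are
#'   assumed to remain in place once adopted. Default 20.
#' @param discount_rate Annual discount rate applied to costs (fraction per
#'   annum). Default 0.03.
#' @param opportunity_cost_per_daly Health opportunity cost \eqn{k}: the
#'   spending (in the evidence base's currency) that displaces one DALY
#'   averted elsewhere in the health system. Default 61 (US$/DALY).
#' @param n_simulations Number of Monte Carlo draws per intervention.
#'   Default 100000.
#' @param seed Integer master seed; per-intervention streams are derived
#'   from it and the intervention id so results do not depend on the order
#'   interventions appear in the workbook.
#' @param interval_level Coverage of the equal-tail uncertainty interval used
#'   to report pNHE ranges and flag decision uncertainty. Default 0.95.
#' @param benefit_discount_rate Optional separate annual discount rate for
#'   health benefits; defaults to `discount_rate`.
#'
#' @return An object of class `"decision_context"`.
#' @examples
#' decision_context()         # defaults: 20 years, 3% p.a., US$61/DALY
#' decision_context(time_horizon_years = 1, discount_rate = 0)
#' @export
decision_context <- function(time_horizon_years = 20L,
                             discount_rate = 0.03,
                             opportunity_cost_per_daly = 61,
                             n_simulations = 1e5L,
                             seed = 1L,
                             interval_level = 0.95,
                             benefit_discount_rate = NULL) {
  time_horizon_years <- as.integer(time_horizon_years)
  if (is.na(time_horizon_years) || time_horizon_years < 1L)
    stop("time_horizon_years must be an integer >= 1", call. = FALSE)
  if (!is.finite(discount_rate) || discount_rate < 0)
    stop("discount_rate must be >= 0", call. = FALSE)
  if (!is.finite(opportunity_cost_per_daly) || opportunity_cost_per_daly <= 0)
    stop("opportunity_cost_per_daly must be > 0", call. = FALSE)
  n_simulations <- as.integer(n_simulations)
  if (is.na(n_simulations) || n_simulations < 1L)
    stop("n_simulations must be >= 1", call. = FALSE)
  if (!is.finite(interval_level) || interval_level <= 0 || interval_level >= 1)
    stop("interval_level must lie in (0, 1)", call. = FALSE)
  if (is.null(benefit_discount_rate)) benefit_discount_rate <- discount_rate
  if (!is.finite(benefit_discount_rate) || benefit_discount_rate < 0)
    stop("benefit_discount_rate must be >= 0", call. = FALSE)
  structure(
    list(
      time_horizon_years = time_horizon_years,
      discount_rate = discount_rate,
      benefit_discount_rate = benefit_discount_rate,
      opportunity_cost_per_daly = opportunity_cost_per_daly,
      n_simulations = n_simulations,
      seed = as.integer(seed),
      interval_level = interval_level
    ),
    class = "decision_context"
  )
}

#' @export
print.decision_context <- function(x, ...) {
  cat("Decision context\n")
  cat(sprintf("  time horizon:        %d years\n", x$time_horizon_years))
  if (x$benefit_discount_rate == x$discount_rate) {
    cat(sprintf("  discount rate:       %.4g per annum\n", x$discount_rate))
  } else {
    cat(sprintf("  discount rate:       %.4g (costs), %.4g (benefits)\n",
                x$discount_rate, x$benefit_discount_rate))
  }
  cat(sprintf("  opportunity cost k:  %.4g per DALY averted\n",
              x$opportunity_cost_per_daly))
  cat(sprintf("  simulations:         %d (seed %d), interval level %.2f\n",
              x$n_simulations, x$seed, x$interval_level))
  invisible(x)
}
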