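#' Summarise a pNHE distribution
#'
#' Mean and equal-tail empirical quantiles (type 7: linear interpolation of
#' order statistics) of a draw vector.
#'
#' @param draws Numeric vector of pNHE draws, or a `pnhe_draws` object.
#' @param level Interval coverage in (0, 1).
#' @return Named numeric vector `c(mean, lower, upper)`.
#' @export
summarize_pnhe <- function(draws, level = 0.95) {
  if (inherits(draws, "pnhe_draws")) draws <- draws$draws
  stopifnot(length(draws) >= 1, level > 0, level < 1)
  alpha <- (1 - level) / 2
  q <- stats::quantile(draws, probs = c(alpha, 1 - alpha), names = FALSE,
                       type = 7)
  c(mean = mean(draws), lower = q[1], upper = q[2])
}

#' Classify the inclusion decision and its uncertainty
#'
#' An intervention is included when its expected pNHE is strictly positive
#' (more health generated than displaced). The decision is flagged uncertain
#' when the uncertainty interval spans zero — the range of plausible pNHE
#' values runs from net losses to net gains, so current evidence could
#' support either inclusion or exclusion.
#'
#' @param summary Named vector from [summarize_pnhe()] (or any vector with
#'   elements `mean`, `lower`, `upper`).
#' @return List with elements `decision` (`"include"`/`"exclude"`) and
#'   `decision_uncertain` (logical).
#' @export
classify_decision <- function(summary) {
  m <- unname(summary["mean"]); lo <- unname(summary["lower"])
  hi <- unname(summary["upper"])
  stopifnot(lo <= hi)
  list(decision = if (m > 0) "include" else "exclude",
       decision_uncertain = (lo < 0 && hi > 0))
}

#' Expected value of perfect information (Monte Carlo)
#'
#' The expected net health forgone by deciding under current uncertainty:
#' with perfect information the better of include/exclude is chosen in every
#' state of the world, worth `mean(pmax(draws, 0))`; under current evidence
#' the single better action is worth `max(mean(draws), 0)`. The difference is
#' the EVPI, in net DALYs averted, clamped at zero against floating rounding.
#'
#' @param draws Numeric vector of pNHE draws, or a `pnhe_draws` object.
#' @return EVPI in net DALYs averted (non-negative scalar).
#' @examples
#' evpi_mc(c(-1, 1))   # 0.5: half the states lose 1 by including
#' evpi_mc(c(2, 3, 4)) # 0: inclusion is correct in every state
#' @export
evpi_mc <- function(draws) {
  if (inherits(draws, "pnhe_draws")) draws <- draws$draws
  stopifnot(length(draws) >= 1)
  max(0, mean(pmax(draws, 0)) - max(mean(draws), 0))
}

#' Closed-form EVPI for a normal pNHE distribution
#'
#' For pNHE ~ Normal(mu, sigma^2) the EVPI has the closed form
#' \eqn{\sigma \phi(\mu/\sigma) - |\mu| \Phi(-|\mu|/\sigma)}. Used as the
#' analytic oracle against which the Monte Carlo estimator is checked; exact
#' because the population net health effect is a linear map of a bivariate
#' normal cost/benefit pair and hence itself normal.
#'
#' @param mu Mean pNHE (net DALYs averted).
#' @param sigma Standard deviation of pNHE (`>= 0`).
#' @return EVPI in net DALYs averted.
#' @examples
#' evpi_normal(0, 1)  # 0.39894 = dnorm(0)
#' evpi_normal(1, 1)  # 0.08332
#' @export
evpi_normal <- function(mu, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(0)
  max(0, sigma * stats::dnorm(mu / sigma) -
        abs(mu) * stats::pnorm(-abs(mu) / sigma))
}

#' Rank interventions for package design and research prioritisation
#'
#' Produces the three orderings used to read a VOI analysis: by expected
#' population incremental health benefit (gross of costs), by expected pNHE,
#' and the research-value view that keeps the pNHE ordering with EVPI
#' attached (so the value of research can be read against the adoption
#' ranking), plus an auxiliary strict EVPI-descending ordering. All ties are
#' broken by intervention id ascending.
#'
#' @param results Data frame with one row per intervention, containing at
#'   least `intervention_id`, `expected_pop_benefit`, `expected_pnhe`,
#'   `evpi`.
#' @return Named list of data frames: `by_population_benefit`, `by_pnhe`,
#'   `research_value` (pNHE order), `by_evpi` (strict EVPI order).
#' @export
rank_interventions <- function(results) {
  stopifnot(nrow(results) >= 1)
  ord <- function(key) {
    results[order(-results[[key]], results$intervention_id), , drop = FALSE]
  }
  by_benefit <- ord("expected_pop_benefit")
  by_pnhe <- ord("expected_pnhe")
  list(by_population_benefit = by_benefit,
       by_pnhe = by_pnhe,
       research_value = by_pnhe,
       by_evpi = ord("evpi"))
}
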