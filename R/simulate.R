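#' Discounted annuity factor over a delivery horizon
#'
#' Converts an annual effect into its discounted total over `T` years of
#' delivery, with the first year undiscounted:
#' \eqn{A = \sum_{t=0}^{T-1} (1 + r)^{-t}}.
#'
#' @param time_horizon_years Integer horizon `T >= 1`.
#' @param discount_rate Annual rate `r >= 0`.
#' @return The annuity factor (dimensionless scalar).
#' @examples
#' annuity_factor(1, 0.03)   # 1
#' annuity_factor(20, 0)     # 20
#' annuity_factor(20, 0.03)  # 15.3238
#' @export
annuity_factor <- function(time_horizon_years, discount_rate) {
  stopifnot(time_horizon_years >= 1, discount_rate >= 0)
  sum((1 + discount_rate)^(-(seq_len(time_horizon_years) - 1)))
}

#' Per-patient net health effect
#'
#' Expresses spending as health forgone at the opportunity-cost rate `k` and
#' nets it off the health gained:
#' `delta_benefit - delta_cost / k` (net DALYs averted per patient).
#'
#' @param delta_benefit Incremental DALYs averted per patient.
#' @param delta_cost Incremental cost per patient (currency).
#' @param k Health opportunity cost (currency per DALY averted), `> 0`.
#' @return Net DALYs averted per patient.
#' @examples
#' per_patient_nhe(2, 61, 61)   # 1: every $61 spent displaces one DALY
#' @export
per_patient_nhe <- function(delta_benefit, delta_cost, k) {
  stopifnot(k > 0)
  delta_benefit - delta_cost / k
}

#' Scale a per-patient effect to the population and horizon
#'
#' @param nhe_pp Net DALYs averted per patient.
#' @param eligible_population Annual eligible cohort size `N`.
#' @param coverage Achievable coverage fraction `c`.
#' @param annuity Annuity factor `A` (see [annuity_factor()]).
#' @return Population net DALYs averted over the horizon,
#'   `nhe_pp * N * c * A`.
#' @export
population_scale <- function(nhe_pp, eligible_population, coverage, annuity) {
  stopifnot(eligible_population >= 0, coverage >= 0, coverage <= 1,
            annuity > 0)
  nhe_pp * eligible_population * coverage * annuity
}

#' Derive a per-intervention random seed
#'
#' Hashes the intervention id into a stable offset added to the master seed,
#' so each intervention draws from its own reproducible stream regardless of
#' the order interventions are processed.
#'
#' @param seed Master integer seed.
#' @param id Intervention id.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, id) {
  codes <- utf8ToInt(as.character(id))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 + h) %% 2147480009)
}

#' Sample joint draws of incremental cost and benefit
#'
#' For the bivariate-normal family draws are generated from two standard
#' normal streams combined through the Cholesky factor of the correlation;
#' for the empirical family the stored pairs are resampled with replacement
#' and recentred to the point-estimate means. Deterministic given `seed`.
#'
#' @param ju A [joint_uncertainty()].
#' @param mean_cost,mean_benefit Point-estimate means the draws are centred
#'   on.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Data frame with columns `delta_cost`, `delta_benefit` and `n`
#'   rows.
#' @export
sample_joint <- function(ju, mean_cost, mean_benefit, n, seed) {
  stopifnot(inherits(ju, "joint_uncertainty"), n >= 1)
  if (abs(ju$correlation) > 1)
    stop("correlation must lie in [-1, 1]", call. = FALSE)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (ju$family == "empirical") {
    idx <- sample.int(nrow(ju$sample), n, replace = TRUE)
    dc <- ju$sample$delta_cost[idx]
    de <- ju$sample$delta_benefit[idx]
    dc <- dc - mean(ju$sample$delta_cost) + mean_cost
    de <- de - mean(ju$sample$delta_benefit) + mean_benefit
    return(data.frame(delta_cost = dc, delta_benefit = de))
  }
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rho <- ju$correlation
  data.frame(
    delta_cost = mean_cost + ju$sd_cost * z1,
    delta_benefit = mean_benefit +
      ju$sd_benefit * (rho * z1 + sqrt(max(0, 1 - rho^2)) * z2)
  )
}

#' Simulate the population net health effect distribution
#'
#' Draws per-patient incremental cost/benefit pairs from the intervention's
#' joint uncertainty, converts each pair to a per-patient net health effect
#' at the opportunity cost `k`, and scales by the eligible population,
#' coverage and discounted horizon. Cost is converted to the DALY scale
#' (division by `k`) before the draw is assembled, so rescaling every cost
#' quantity and `k` by a common factor reproduces the draws exactly.
#'
#' @param record An [intervention()].
#' @param ju The intervention's [joint_uncertainty()].
#' @param ctx A [decision_context()].
#' @param population_model `"annual_cohort"` (default): `N` is an annual
#'   eligible cohort treated every year of the horizon, so the per-patient
#'   effect is multiplied by the discounted annuity; `"prevalent_pool"`:
#'   a one-off pool treated once (annuity replaced by 1).
#' @return An object of class `"pnhe_draws"`: list with `intervention_id`,
#'   `draws` (net DALYs averted, population scale), `scale_factor`
#'   (`A * N * c`) and `seed_used`.
#' @export
simulate_pnhe <- function(record, ju, ctx,
                          population_model = c("annual_cohort",
                                               "prevalent_pool")) {
  population_model <- match.arg(population_model)
  stopifnot(inherits(record, "intervention"),
            inherits(ju, "joint_uncertainty"),
            inherits(ctx, "decision_context"))
  if (population_model == "annual_cohort") {
    A_e <- annuity_factor(ctx$time_horizon_years, ctx$benefit_discount_rate)
    A_c <- if (ctx$benefit_discount_rate == ctx$discount_rate) A_e
    else annuity_factor(ctx$time_horizon_years, ctx$discount_rate)
  } else {
    A_e <- A_c <- 1
  }
  k <- ctx$opportunity_cost_per_daly
  seed <- derive_seed(ctx$seed, record$id)
  # work on the DALY scale: cost mean/sd divided by k once, so common
  # rescaling of (costs, k) cancels exactly in floating point
  ju_h <- ju
  mean_cost_h <- record$delta_cost_pp / k
  if (ju$family == "bivariate_normal") {
    ju_h$sd_cost <- ju$sd_cost / k
  } else {
    ju_h$sample <- data.frame(delta_cost = ju$sample$delta_cost / k,
                              delta_benefit = ju$sample$delta_benefit)
  }
  pairs <- sample_joint(ju_h, mean_cost_h, record$delta_benefit_pp,
                        ctx$n_simulations, seed)
  scale_factor <- A_e * record$eligible_population * record$coverage
  if (A_c == A_e) {
    draws <- (pairs$delta_benefit - pairs$delta_cost) * scale_factor
  } else {
    # separate discounting of costs and benefits
    nc <- record$eligible_population * record$coverage
    draws <- (A_e * pairs$delta_benefit - A_c * pairs$delta_cost) * nc
  }
  structure(
    list(intervention_id = record$id, draws = draws,
         scale_factor = scale_factor, seed_used = seed),
    class = "pnhe_draws"
  )
}

#' @export
print.pnhe_draws <- function(x, ...) {
  cat(sprintf("pNHE draws for '%s': n = %d, mean = %.6g net DALYs\n",
              x$intervention_id, length(x$draws), mean(x$draws)))
  invisible(x)
}
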