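#' Value-of-information analysis for health benefits package design
#'
#' The package's main fitting function. Takes an evidence base — global
#' decision parameters, per-intervention point estimates, and whatever
#' sensitivity-analysis summaries the source studies reported — and runs the
#' full pipeline:
#'
#' 1. reconstructs the joint distribution of per-patient incremental cost
#'    and incremental benefit for every intervention with evidence
#'    ([reconstruct_uncertainty()]); correlations absent from a medium are
#'    filled with the pooled average of the informed set;
#' 2. pools the reconstructed uncertainty ([pool_uncertainty()]) and imputes
#'    it for interventions lacking evidence ([impute_uncertainty()],
#'    exploratory analysis);
#' 3. simulates the population net health effect (pNHE) distribution of each
#'    intervention over the discounted delivery horizon
#'    ([simulate_pnhe()]);
#' 4. summarises each distribution, classifies the inclusion decision and
#'    its uncertainty, and computes the expected value of perfect
#'    information ([evpi_mc()]) in net DALYs averted.
#'
#' @param eb An [evidence_base()].
#' @param n_simulations,seed,interval_level Optional overrides of the
#'   corresponding `eb$context` settings.
#' @param imputation_mode `"absolute"` (pooled standard deviations copied
#'   directly, the default) or `"relative"` (pooled coefficients of
#'   variation rescaled by each intervention's point estimates).
#' @param pairs_mode `"parametric"` or `"empirical"` handling of raw
#'   simulation / scatter payloads.
#' @param range_convention `"extremes_uniform"` or `"interval95"` reading of
#'   univariate and tornado ranges.
#' @param tornado_attribution Margin absorbing tornado ICER uncertainty
#'   (`"cost"` or `"benefit"`).
#' @param population_model `"annual_cohort"` (annuity-weighted annual
#'   cohorts) or `"prevalent_pool"` (one-off pool, no annuity).
#' @param keep_draws Keep the per-intervention draw vectors on the returned
#'   object (memory scales with `n_simulations * n_interventions`).
#'
#' @return An object of class `"voi_hbp"`: a list with
#'   \describe{
#'     \item{results}{data frame, one row per intervention: point estimates,
#'       reconstructed/imputed `sd_cost`, `sd_benefit`, `correlation`,
#'       `provenance`, `expected_pop_benefit` (gross of costs),
#'       `expected_pnhe`, `pnhe_lower`/`pnhe_upper`, `decision`,
#'       `decision_uncertain`, `prob_cost_effective`, `evpi`, `seed_used`.}
#'     \item{pooled}{the pooled uncertainty used for imputation (or `NULL`).}
#'     \item{context}{the decision context actually used.}
#'     \item{settings}{the reconstruction/imputation switches.}
#'     \item{draws}{named list of draw vectors when `keep_draws = TRUE`.}
#'   }
#' @examples
#' eb <- evidence_base(
#'   decision_context(n_simulations = 2000, seed = 7),
#'   list(
#'     intervention("mc", "male circumcision-like", delta_cost_pp = 60,
#'                  delta_benefit_pp = 1.1, eligible_population = 5e4,
#'                  coverage = 0.5,
#'                  evidence = evidence_mean_se(40, 0.8, rho = 0.1)),
#'     intervention("tb", "clear best buy", delta_cost_pp = 30,
#'                  delta_benefit_pp = 2, eligible_population = 1e5,
#'                  coverage = 0.8,
#'                  evidence = evidence_mean_ci(c(10, 50), c(1.6, 2.4)))))
#' fit <- voi_hbp(eb)
#' fit
#' @export
voi_hbp <- function(eb,
                    n_simulations = NULL, seed = NULL, interval_level = NULL,
                    imputation_mode = c("absolute", "relative"),
                    pairs_mode = c("parametric", "empirical"),
                    range_convention = c("extremes_uniform", "interval95"),
                    tornado_attribution = c("cost", "benefit"),
                    population_model = c("annual_cohort", "prevalent_pool"),
                    keep_draws = FALSE) {
  imputation_mode <- match.arg(imputation_mode)
  pairs_mode <- match.arg(pairs_mode)
  range_convention <- match.arg(range_convention)
  tornado_attribution <- match.arg(tornado_attribution)
  population_model <- match.arg(population_model)
  if (!inherits(eb, "evidence_base"))
    stop("eb must be an evidence_base", call. = FALSE)
  diag <- validate_evidence_base(eb)
  if (nrow(diag) > 0)
    stop("evidence base failed validation:\n",
         paste(sprintf("  %s/%s: %s", diag$intervention_id, diag$field,
                       diag$message), collapse = "\n"), call. = FALSE)
  ctx <- eb$context
  if (!is.null(n_simulations)) ctx$n_simulations <- as.integer(n_simulations)
  if (!is.null(seed)) ctx$seed <- as.integer(seed)
  if (!is.null(interval_level)) ctx$interval_level <- interval_level
  ivs <- eb$interventions
  has_ev <- vapply(ivs, function(iv) !is.null(iv$evidence), logical(1))

  recon <- function(iv, pooled_rho)
    reconstruct_uncertainty(iv, pooled_rho = pooled_rho,
                            pairs_mode = pairs_mode,
                            range_convention = range_convention,
                            tornado_attribution = tornado_attribution)

  # pass 1: media whose payload pins the correlation (no pooled rho needed)
  jus <- vector("list", length(ivs)); names(jus) <- names(ivs)
  self_rho <- vapply(ivs, function(iv) medium_carries_rho(iv$evidence),
                     logical(1))
  for (id in names(ivs)[self_rho])
    jus[[id]] <- recon(ivs[[id]], pooled_rho = NULL)
  pooled_rho <- if (any(self_rho)) {
    mean(vapply(jus[self_rho], `[[`, numeric(1), "correlation"))
  } else NULL
  # pass 2: media needing a correlation default
  for (id in names(ivs)[has_ev & !self_rho])
    jus[[id]] <- recon(ivs[[id]], pooled_rho = pooled_rho)

  pooled <- NULL
  if (any(has_ev)) {
    inf_ids <- names(ivs)[has_ev]
    pooled <- pool_uncertainty(
      jus[inf_ids],
      vapply(ivs[inf_ids], `[[`, numeric(1), "delta_cost_pp"),
      vapply(ivs[inf_ids], `[[`, numeric(1), "delta_benefit_pp"))
  }
  if (any(!has_ev)) {
    if (is.null(pooled))
      stop("no intervention carries sensitivity-analysis evidence: ",
           "cannot pool values for the exploratory imputation", call. = FALSE)
    for (id in names(ivs)[!has_ev])
      jus[[id]] <- impute_uncertainty(ivs[[id]], pooled,
                                      mode = imputation_mode)
  }

  A <- if (population_model == "annual_cohort")
    annuity_factor(ctx$time_horizon_years, ctx$benefit_discount_rate)
  else 1
  k <- ctx$opportunity_cost_per_daly
  draws_list <- if (keep_draws) list() else NULL
  rows <- lapply(names(ivs), function(id) {
    iv <- ivs[[id]]; ju <- jus[[id]]
    pd <- simulate_pnhe(iv, ju, ctx, population_model = population_model)
    if (keep_draws) draws_list[[id]] <<- pd$draws
    s <- summarize_pnhe(pd$draws, ctx$interval_level)
    cls <- classify_decision(s)
    data.frame(
      intervention_id = id, name = iv$name,
      medium = if (is.null(iv$evidence)) "none" else iv$evidence$medium,
      provenance = ju$provenance,
      delta_cost_pp = iv$delta_cost_pp,
      delta_benefit_pp = iv$delta_benefit_pp,
      eligible_population = iv$eligible_population, coverage = iv$coverage,
      sd_cost = ju$sd_cost, sd_benefit = ju$sd_benefit,
      correlation = ju$correlation,
      expected_pop_benefit =
        A * iv$eligible_population * iv$coverage * iv$delta_benefit_pp,
      expected_pnhe = unname(s["mean"]),
      pnhe_lower = unname(s["lower"]), pnhe_upper = unname(s["upper"]),
      decision = cls$decision, decision_uncertain = cls$decision_uncertain,
      prob_cost_effective = mean(pd$draws > 0),
      evpi = evpi_mc(pd$draws),
      seed_used = pd$seed_used,
      stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(
    list(results = results, pooled = pooled, context = ctx,
         uncertainty = jus,
         settings = list(imputation_mode = imputation_mode,
                         pairs_mode = pairs_mode,
                         range_convention = range_convention,
                         tornado_attribution = tornado_attribution,
                         population_model = population_model),
         draws = draws_list,
         annuity = A, opportunity_cost = k),
    class = "voi_hbp"
  )
}

#' @export
print.voi_hbp <- function(x, ...) {
  r <- x$results
  cat(sprintf("VOI analysis of %d intervention(s)\n", nrow(r)))
  cat(sprintf("  horizon %d years (annuity %.4f), k = %.4g per DALY, n = %d draws\n",
              x$context$time_horizon_years, x$annuity, x$opportunity_cost,
              x$context$n_simulations))
  cat(sprintf("  include: %d, exclude: %d, decisions uncertain: %d, imputed: %d\n",
              sum(r$decision == "include"), sum(r$decision == "exclude"),
              sum(r$decision_uncertain), sum(r$provenance == "imputed")))
  top <- r[order(-r$evpi, r$intervention_id), , drop = FALSE]
  top <- utils::head(top[, c("intervention_id", "expected_pnhe", "decision",
                             "decision_uncertain", "evpi")], 5L)
  cat("  top research priorities (by EVPI, net DALYs averted):\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
summary.voi_hbp <- function(object, ...) {
  structure(list(fit = object,
                 rankings = rank_interventions(object$results)),
            class = "summary.voi_hbp")
}

#' @export
print.summary.voi_hbp <- function(x, ...) {
  print(x$fit)
  cols <- c("intervention_id", "expected_pnhe", "pnhe_lower", "pnhe_upper",
            "prob_cost_effective", "evpi", "provenance")
  cat("\nInterventions by expected pNHE (net DALYs averted):\n")
  print(x$rankings$by_pnhe[, cols], row.names = FALSE)
  invisible(x)
}

#' Bar charts of the three rankings
#'
#' Plots expected population incremental health benefit, expected pNHE (both
#' with uncertainty error bars where available) or the value of research
#' (EVPI) per intervention, ordered as in [rank_interventions()].
#'
#' @param x A `voi_hbp` fit.
#' @param which One of `"pnhe"`, `"benefit"`, `"evpi"`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.voi_hbp <- function(x, which = c("pnhe", "benefit", "evpi"), ...) {
  which <- match.arg(which)
  rk <- rank_interventions(x$results)
  df <- switch(which, pnhe = rk$by_pnhe, benefit = rk$by_population_benefit,
               evpi = rk$research_value)
  vals <- switch(which, pnhe = df$expected_pnhe,
                 benefit = df$expected_pop_benefit, evpi = df$evpi)
  ylab <- switch(which,
                 pnhe = "expected pNHE (net DALYs averted)",
                 benefit = "expected population health benefit (DALYs)",
                 evpi = "value of research (net DALYs averted)")
  mid <- graphics::barplot(vals, names.arg = df$intervention_id, las = 2,
                           ylab = ylab, ...)
  if (which == "pnhe") {
    graphics::arrows(mid, df$pnhe_lower, mid, df$pnhe_upper, angle = 90,
                     code = 3, length = 0.03)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}

#' Re-simulate pNHE draws from a fitted VOI analysis
#'
#' Regenerates the per-intervention population net health effect draws from
#' the reconstructed (or imputed) joint uncertainty held on the fit, under a
#' caller-chosen seed and draw count. With the fit's own seed and draw count
#' this reproduces the distribution the reported summaries were computed
#' from.
#'
#' @param object A `voi_hbp` fit.
#' @param nsim Draws per intervention (default: the fit's `n_simulations`).
#' @param seed Master seed (default: the fit's seed).
#' @param ... Unused.
#' @return Named list of numeric draw vectors, one per intervention.
#' @export
simulate.voi_hbp <- function(object, nsim = NULL, seed = NULL, ...) {
  ctx <- object$context
  if (!is.null(nsim)) ctx$n_simulations <- as.integer(nsim)
  if (!is.null(seed)) ctx$seed <- as.integer(seed)
  out <- lapply(object$results$intervention_id, function(id) {
    r <- object$results[object$results$intervention_id == id, ]
    iv <- intervention(id, r$name, r$delta_cost_pp, r$delta_benefit_pp,
                       r$eligible_population, r$coverage)
    simulate_pnhe(iv, object$uncertainty[[id]], ctx,
                  population_model = object$settings$population_model)$draws
  })
  names(out) <- object$results$intervention_id
  out
}
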