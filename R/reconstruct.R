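#' @title Reconstructing joint uncertainty from sensitivity-analysis summaries
#'
#' @description
#' Published cost-effectiveness studies rarely report the joint distribution
#' of incremental cost and incremental benefit directly; they report one of a
#' handful of summary media. The functions below invert each medium back to a
#' [joint_uncertainty()]: standard deviations \eqn{\sigma_C}, \eqn{\sigma_E}
#' and correlation \eqn{\rho} on the per-patient incremental scale (or, for
#' raw simulations, an empirical joint sample). [reconstruct_uncertainty()]
#' dispatches on the medium tag of an intervention's evidence payload.
#'
#' @name reconstruction
NULL

default_rho <- function(rho, pooled_rho) {
  if (!is.null(rho)) return(rho)
  if (is.null(pooled_rho) || !is.finite(pooled_rho)) {
    warning("no correlation reported and no pooled value available; using 0",
            call. = FALSE)
    return(0)
  }
  pooled_rho
}

#' @describeIn reconstruction Standard errors map to standard deviations
#'   directly (the reported SE of the mean incremental quantities is the
#'   spread the probabilistic analysis propagates).
#' @param se_cost,se_benefit Reported standard errors (currency / DALYs).
#' @param rho Correlation; when `NULL` the pooled average `pooled_rho` is
#'   substituted (0 with a warning when no pooled value exists).
#' @param pooled_rho Pooled average correlation from the informed
#'   interventions, used when the medium does not carry one.
#' @export
from_mean_se <- function(se_cost, se_benefit, rho = NULL, pooled_rho = NULL) {
  if (se_cost < 0 || se_benefit < 0)
    stop("standard errors must be non-negative", call. = FALSE)
  rho <- default_rho(rho, pooled_rho)
  diags <- character()
  if (se_cost == 0 || se_benefit == 0) {
    if (rho != 0) diags <- "degenerate margin: correlation forced to 0"
    rho <- 0
  }
  joint_uncertainty(se_cost, se_benefit, rho, diagnostics = diags)
}

#' @describeIn reconstruction Symmetric normal intervals: each margin's
#'   standard deviation is the interval width over twice the standard-normal
#'   quantile at `(1 + level) / 2`. Asymmetry of the reported interval around
#'   the point estimate cannot be represented by this symmetric family and is
#'   not checked here (the point estimates live on the intervention record);
#'   a zero-width interval yields a degenerate margin.
#' @param ci_cost,ci_benefit Length-2 `(lower, upper)` intervals.
#' @param level Nominal coverage of the intervals.
#' @export
from_mean_ci <- function(ci_cost, ci_benefit, level = 0.95, rho = NULL,
                         pooled_rho = NULL) {
  stopifnot(length(ci_cost) == 2L, length(ci_benefit) == 2L)
  if (ci_cost[1] > ci_cost[2] || ci_benefit[1] > ci_benefit[2])
    stop("interval must satisfy lower <= upper", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("interval level must lie in (0, 1)", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  sd_cost <- diff(ci_cost) / (2 * z)
  sd_benefit <- diff(ci_benefit) / (2 * z)
  rho <- default_rho(rho, pooled_rho)
  diags <- character()
  if (sd_cost == 0 || sd_benefit == 0) {
    if (rho != 0) diags <- "degenerate margin: correlation forced to 0"
    rho <- 0
  }
  joint_uncertainty(sd_cost, sd_benefit, rho, diagnostics = diags)
}

#' @describeIn reconstruction Raw probabilistic simulations or digitized
#'   scatterplot points. Parametric mode summarises the pairs by their sample
#'   moments (unbiased variances, sample correlation); empirical mode retains
#'   the pairs for resampling.
#' @param delta_cost,delta_benefit Simulated incremental cost/benefit pairs.
#' @param mode `"parametric"` (moment summary, bivariate normal) or
#'   `"empirical"` (retain pairs for resampling).
#' @export
from_raw_pairs <- function(delta_cost, delta_benefit,
                           mode = c("parametric", "empirical")) {
  mode <- match.arg(mode)
  stopifnot(length(delta_cost) == length(delta_benefit))
  n <- length(delta_cost)
  if (n < 3L)
    stop("at least 3 pairs are required to estimate joint uncertainty",
         call. = FALSE)
  sd_c <- stats::sd(delta_cost)
  sd_e <- stats::sd(delta_benefit)
  diags <- character()
  if (sd_c == 0 || sd_e == 0) {
    rho <- 0
    diags <- "degenerate margin: correlation set to 0"
    warning("zero variance in one margin; correlation set to 0",
            call. = FALSE)
  } else {
    rho <- stats::cor(delta_cost, delta_benefit)
  }
  if (mode == "parametric")
    return(joint_uncertainty(sd_c, sd_e, rho, diagnostics = diags))
  joint_uncertainty(sd_c, sd_e, rho, family = "empirical",
                    sample = data.frame(delta_cost = delta_cost,
                                        delta_benefit = delta_benefit),
                    diagnostics = diags)
}

range_to_sd <- function(width, range_convention) {
  switch(range_convention,
         extremes_uniform = abs(width) / sqrt(12),
         interval95 = abs(width) / (2 * stats::qnorm(0.975)),
         stop("unknown range convention: ", range_convention, call. = FALSE))
}

#' @describeIn reconstruction Univariate (one-at-a-time) sensitivity table.
#'   Each varied parameter contributes a variance to each margin and a signed
#'   covariance given by the co-movement of cost and benefit across its
#'   range; contributions are summed assuming the varied parameters are
#'   independent. Under `extremes_uniform` a range of width `w` contributes
#'   variance `w^2 / 12` (endpoints read as the extremes of a uniform); under
#'   `interval95` the half-range is read as a 95% normal half-interval.
#' @param rows Data frame with columns `param_id`, `dc_low`, `dc_high`,
#'   `de_low`, `de_high` (values at each parameter's low/high setting).
#' @param range_convention `"extremes_uniform"` or `"interval95"`.
#' @export
from_univariate_table <- function(rows,
                                  range_convention = c("extremes_uniform",
                                                       "interval95")) {
  range_convention <- match.arg(range_convention)
  rows <- as.data.frame(rows)
  if (nrow(rows) < 1L)
    stop("univariate table is empty", call. = FALSE)
  dcw <- rows$dc_high - rows$dc_low   # signed co-movement widths
  dew <- rows$de_high - rows$de_low
  sd_c_j <- vapply(dcw, range_to_sd, numeric(1), range_convention)
  sd_e_j <- vapply(dew, range_to_sd, numeric(1), range_convention)
  var_c <- sum(sd_c_j^2)
  var_e <- sum(sd_e_j^2)
  # covariance contribution keeps the sign of the co-movement
  cov_j <- sign(dcw * dew) * sd_c_j * sd_e_j
  sd_c <- sqrt(var_c)
  sd_e <- sqrt(var_e)
  diags <- character()
  if (sd_c == 0 || sd_e == 0) {
    rho <- 0
    if (sd_c == 0 && sd_e == 0) diags <- "all ranges have zero width"
  } else {
    rho <- sum(cov_j) / (sd_c * sd_e)
    rho <- min(1, max(-1, rho))
  }
  joint_uncertainty(sd_c, sd_e, rho, diagnostics = diags)
}

#' @describeIn reconstruction Tornado plot of ICERs. Bar widths are converted
#'   to a total ICER variance under the chosen range convention (independent
#'   parameters). Because the medium carries no information splitting the
#'   uncertainty between cost and benefit, it is attributed to a single
#'   margin: `attribution = "cost"` (default) sets
#'   `sd_cost = sd(ICER) * |delta_benefit_base|` with the benefit held fixed;
#'   `attribution = "benefit"` maps the 95% ICER interval through
#'   `delta_e = delta_cost_base / ICER` and reads the half-width of the
#'   resulting benefit interval as a 95% normal half-interval.
#' @param base_icer Point-estimate ICER (currency per DALY averted).
#' @param bars Data frame with columns `param_id`, `icer_low`, `icer_high`.
#' @param delta_benefit_base Point-estimate incremental benefit (nonzero).
#' @param attribution Which margin absorbs the ICER uncertainty.
#' @export
from_tornado_icer <- function(base_icer, bars, delta_benefit_base,
                              attribution = c("cost", "benefit"),
                              range_convention = c("extremes_uniform",
                                                   "interval95")) {
  attribution <- match.arg(attribution)
  range_convention <- match.arg(range_convention)
  bars <- as.data.frame(bars)
  if (nrow(bars) < 1L) stop("tornado payload is empty", call. = FALSE)
  if (delta_benefit_base == 0)
    stop("base incremental benefit is zero: ICER undefined", call. = FALSE)
  widths <- bars$icer_high - bars$icer_low
  sd_icer <- sqrt(sum(vapply(widths, range_to_sd, numeric(1),
                             range_convention)^2))
  if (sd_icer == 0)
    return(joint_uncertainty(0, 0, 0,
                             diagnostics = "zero-width tornado bars"))
  if (attribution == "cost")
    return(joint_uncertainty(sd_icer * abs(delta_benefit_base), 0, 0))
  # benefit attribution: invert the 95% ICER interval through dE = dC / ICER
  z <- stats::qnorm(0.975)
  delta_cost_base <- base_icer * delta_benefit_base
  icer_lo <- base_icer - z * sd_icer
  icer_hi <- base_icer + z * sd_icer
  if (icer_lo <= 0 && icer_hi >= 0)
    stop("ICER interval spans zero: cannot attribute uncertainty to the ",
         "benefit margin (use attribution = 'cost')", call. = FALSE)
  e_ends <- sort(delta_cost_base / c(icer_lo, icer_hi))
  sd_e <- (e_ends[2] - e_ends[1]) / (2 * z)
  joint_uncertainty(0, sd_e, 0)
}

# --- fitting sd_cost, sd_benefit from a one-dimensional ICER summary ------

# Bounded least squares of a model CDF against target points, multi-started
# from deterministic initial values. theta = (sd_cost, sd_benefit).
fit_icer_cdf <- function(target_t, target_p, mean_cost, mean_benefit,
                         rho_fixed, truncated = FALSE) {
  if (mean_benefit == 0)
    stop("mean incremental benefit is zero: ICER undefined", call. = FALSE)
  model_p <- function(theta) {
    p <- picer(target_t, mean_cost, mean_benefit, theta[1], theta[2],
               rho_fixed)
    if (truncated) {
      span <- p[length(p)] - p[1]
      if (span <= 0) return(rep(0.5, length(p)))
      p <- (p - p[1]) / span
    }
    p
  }
  obj <- function(theta) sum((model_p(theta) - target_p)^2)
  scale_c <- max(abs(mean_cost), 1e-6)
  scale_e <- max(abs(mean_benefit), 1e-6)
  # ICER spread gives a crude scale for the cost margin when benefit is fixed
  spread <- stats::sd(target_t)
  if (!is.finite(spread) || spread == 0) spread <- scale_c / scale_e
  starts <- list(
    c(spread * abs(mean_benefit), 0.3 * scale_e),
    c(0.5 * scale_c, 0.5 * scale_e),
    c(0.1 * scale_c, 0.1 * scale_e),
    c(spread * abs(mean_benefit) * 0.5, 0.6 * scale_e),
    c(1.0 * scale_c, 0.05 * scale_e)
  )
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(pmax(s, 1e-8), obj, method = "L-BFGS-B",
                            lower = c(1e-8, 1e-8) * c(scale_c, scale_e),
                            upper = c(50 * scale_c, 50 * scale_e),
                            control = list(maxit = 200,
                                           parscale = c(scale_c, scale_e))),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value ||
        (fit$value == best$value && fit$par[1] < best$par[1]))
      best <- fit
  }
  if (is.null(best))
    stop("ICER distribution fit failed: optimizer did not produce a solution",
         call. = FALSE)
  best
}

#' @describeIn reconstruction Histogram of the ICER from a probabilistic
#'   analysis. Fits `(sd_cost, sd_benefit)` by maximising the multinomial
#'   likelihood of the bin counts under the ratio distribution of
#'   `delta_cost / delta_benefit` for a bivariate normal with the given
#'   means and a fixed correlation (the ratio alone cannot identify all
#'   three shape parameters). Bin probabilities are conditioned on the
#'   histogram support, so histograms that clip tail mass remain comparable;
#'   the likelihood weighting keeps the tail bins informative, which a plain
#'   least-squares CDF fit loses once the support is renormalised. The
#'   reported `fit_residual` is the squared distance between the fitted and
#'   observed cumulative bin fractions; above `residual_warn` a poor-fit
#'   diagnostic is attached, never silently discarded.
#' @param bin_edges Ascending ICER bin edges.
#' @param counts Bin counts.
#' @param mean_cost,mean_benefit Point-estimate incremental cost and benefit.
#' @param rho_fixed Correlation held fixed during the fit (default pooled or
#'   0).
#' @param residual_warn Residual sum of squares above which a poor-fit
#'   diagnostic is attached.
#' @export
from_icer_histogram <- function(bin_edges, counts, mean_cost, mean_benefit,
                                rho_fixed = 0, pooled_rho = NULL,
                                residual_warn = 0.01) {
  if (length(bin_edges) != length(counts) + 1L)
    stop("need length(bin_edges) == length(counts) + 1", call. = FALSE)
  if (sum(counts) <= 0) stop("histogram has no mass", call. = FALSE)
  if (is.null(rho_fixed)) rho_fixed <- default_rho(NULL, pooled_rho)
  if (mean_benefit == 0)
    stop("mean incremental benefit is zero: ICER undefined", call. = FALSE)
  nll <- function(theta) {
    p <- picer(bin_edges, mean_cost, mean_benefit, theta[1], theta[2],
               rho_fixed)
    q <- diff(p)
    span <- sum(q)
    if (!is.finite(span) || span <= 0) return(1e10)
    -sum(counts * log(pmax(q / span, 1e-12)))
  }
  scale_c <- max(abs(mean_cost), 1e-6)
  scale_e <- max(abs(mean_benefit), 1e-6)
  starts <- list(c(0.4, 0.3), c(0.8, 0.6), c(0.2, 0.15), c(0.6, 0.45),
                 c(1.0, 0.2))
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(c(s[1] * scale_c, s[2] * scale_e), nll,
                            method = "L-BFGS-B",
                            lower = c(1e-8 * scale_c, 1e-8 * scale_e),
                            upper = c(50 * scale_c, 50 * scale_e),
                            control = list(maxit = 200,
                                           parscale = c(scale_c, scale_e))),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value ||
        (fit$value == best$value && fit$par[1] < best$par[1]))
      best <- fit
  }
  if (is.null(best))
    stop("ICER histogram fit failed: optimizer did not produce a solution",
         call. = FALSE)
  # goodness-of-fit on the cumulative scale, comparable across payloads
  cum <- c(0, cumsum(counts)) / sum(counts)
  p <- picer(bin_edges, mean_cost, mean_benefit, best$par[1], best$par[2],
             rho_fixed)
  span <- p[length(p)] - p[1]
  resid <- if (span > 0) sum(((p - p[1]) / span - cum)^2) else Inf
  diags <- character()
  if (resid > residual_warn)
    diags <- sprintf("poor histogram fit: residual %.3g", resid)
  rho <- if (best$par[1] == 0 || best$par[2] == 0) 0 else rho_fixed
  joint_uncertainty(best$par[1], best$par[2], rho, diagnostics = diags,
                    fit_residual = resid)
}

#' @describeIn reconstruction Cumulative distribution of the ICER reported as
#'   `(icer, cum_prob)` points; same fitting strategy as
#'   [from_icer_histogram()] against the points directly (no support
#'   renormalisation).
#' @param points Data frame with columns `icer`, `cum_prob`.
#' @export
from_icer_cdf <- function(points, mean_cost, mean_benefit, rho_fixed = 0,
                          pooled_rho = NULL, residual_warn = 0.01) {
  points <- as.data.frame(points)
  if (nrow(points) < 3L)
    stop("at least 3 CDF points are required", call. = FALSE)
  points <- points[order(points$icer), , drop = FALSE]
  if (any(diff(points$cum_prob) < 0))
    stop("cumulative probabilities must be non-decreasing", call. = FALSE)
  if (any(points$cum_prob < 0 | points$cum_prob > 1))
    stop("cumulative probabilities must lie in [0, 1]", call. = FALSE)
  if (is.null(rho_fixed)) rho_fixed <- default_rho(NULL, pooled_rho)
  fit <- fit_icer_cdf(points$icer, points$cum_prob, mean_cost, mean_benefit,
                      rho_fixed)
  diags <- character()
  if (fit$value > residual_warn)
    diags <- sprintf("poor CDF fit: residual %.3g", fit$value)
  rho <- if (fit$par[1] == 0 || fit$par[2] == 0) 0 else rho_fixed
  joint_uncertainty(fit$par[1], fit$par[2], rho, diagnostics = diags,
                    fit_residual = fit$value)
}

#' @describeIn reconstruction Cost-effectiveness acceptability curve. Under
#'   bivariate normality the probability of being cost-effective at
#'   willingness-to-pay \eqn{\lambda} is
#'   \eqn{\Phi(m(\lambda) / s(\lambda))} with
#'   \eqn{m(\lambda) = \lambda \bar{\Delta e} - \bar{\Delta c}} and
#'   \eqn{s(\lambda)^2 = \lambda^2 \sigma_E^2 -
#'   2 \lambda \rho \sigma_E \sigma_C + \sigma_C^2}. All three shape
#'   parameters \eqn{(\sigma_C, \sigma_E, \rho)} are recovered by constrained
#'   least squares; because \eqn{s(\lambda)^2} is quadratic in \eqn{\lambda},
#'   inverting the probabilities to the z-scale gives a linear system whose
#'   solution seeds the optimizer. With exactly three distinct
#'   willingness-to-pay values the fit must interpolate the points (residual
#'   below `exact_tol`), otherwise reconstruction fails with the residual
#'   attached.
#' @param exact_tol Maximum residual accepted as "exact" when only three
#'   distinct willingness-to-pay points are supplied.
#' @export
from_ceac <- function(points, mean_cost, mean_benefit, exact_tol = 1e-4,
                      residual_warn = 0.01) {
  points <- as.data.frame(points)
  points <- points[order(points$wtp), , drop = FALSE]
  lambda <- points$wtp
  p <- points$prob_ce
  if (length(unique(lambda)) < 3L)
    stop("at least 3 distinct willingness-to-pay values are required",
         call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (all(p >= 1 - 1e-12) || all(p <= 1e-12))
    stop("CEAC is saturated at 0 or 1 everywhere: the uncertainty scale is ",
         "unidentifiable from these points", call. = FALSE)
  m <- lambda * mean_benefit - mean_cost
  p_clip <- pmin(1 - 1e-12, pmax(1e-12, p))
  ceac_obj <- function(theta) {
    s2 <- lambda^2 * theta[2]^2 - 2 * lambda * theta[3] * theta[1] * theta[2] +
      theta[1]^2
    s <- sqrt(pmax(s2, 1e-300))
    sum((stats::pnorm(m / s) - p)^2)
  }
  scale_c <- max(abs(mean_cost), 1e-6)
  scale_e <- max(abs(mean_benefit), 1e-6)
  starts <- list(
    c(0.5 * scale_c, 0.5 * scale_e, 0),
    c(0.2 * scale_c, 0.2 * scale_e, 0.5),
    c(scale_c, scale_e, -0.5),
    c(0.1 * scale_c, scale_e, 0),
    c(scale_c, 0.1 * scale_e, 0)
  )
  # linear inversion on the z scale: s(lambda)^2 = a*l^2 - 2*b*l + c
  z <- stats::qnorm(p_clip)
  usable <- is.finite(z) & abs(z) > 1e-8 & sign(z) == sign(m)
  if (sum(usable) >= 3L) {
    s2_obs <- (m[usable] / z[usable])^2
    X <- cbind(lambda[usable]^2, -2 * lambda[usable], 1)
    coefs <- try(stats::lm.fit(X, s2_obs)$coefficients, silent = TRUE)
    if (!inherits(coefs, "try-error") && all(is.finite(coefs)) &&
        coefs[1] > 0 && coefs[3] > 0) {
      sC <- sqrt(coefs[3]); sE <- sqrt(coefs[1])
      r <- coefs[2] / (sC * sE)
      starts <- c(list(c(sC, sE, min(0.999, max(-0.999, r)))), starts)
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, ceac_obj, method = "L-BFGS-B",
                            lower = c(1e-10 * scale_c, 1e-10 * scale_e, -0.999),
                            upper = c(1e4 * scale_c, 1e4 * scale_e, 0.999),
                            control = list(maxit = 200,
                                           parscale = c(scale_c, scale_e, 1))),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value ||
        (fit$value == best$value && fit$par[1] < best$par[1]))
      best <- fit
    if (best$value < 1e-16) break
  }
  if (is.null(best))
    stop("CEAC fit failed: optimizer did not produce a solution",
         call. = FALSE)
  if (length(unique(lambda)) == 3L && best$value > exact_tol)
    stop(sprintf(paste0("CEAC reconstruction failed: three points could not ",
                        "be interpolated (residual %.3g); the probabilities ",
                        "may be inconsistent with the point-estimate means"),
                 best$value), call. = FALSE)
  diags <- character()
  if (best$value > residual_warn)
    diags <- sprintf("poor CEAC fit: residual %.3g", best$value)
  joint_uncertainty(best$par[1], best$par[2],
                    min(1, max(-1, best$par[3])),
                    diagnostics = diags, fit_residual = best$value)
}

#' Reconstruct joint uncertainty for one intervention
#'
#' Dispatches on the medium of the intervention's evidence payload to the
#' medium-specific routine, filling absent correlations from the pooled
#' average of the informed set.
#'
#' @param record An [intervention()] with a non-`NULL` evidence payload.
#' @param pooled_rho Pooled average correlation (see [pool_uncertainty()]),
#'   used where the medium does not carry a correlation.
#' @param pairs_mode Mode for raw-simulation / scatter payloads
#'   (`"parametric"` or `"empirical"`).
#' @param range_convention Convention for univariate and tornado ranges.
#' @param tornado_attribution Margin absorbing tornado ICER uncertainty.
#' @return A [joint_uncertainty()] with `provenance = "reconstructed"`.
#' @export
reconstruct_uncertainty <- function(record, pooled_rho = NULL,
                                    pairs_mode = c("parametric", "empirical"),
                                    range_convention = c("extremes_uniform",
                                                         "interval95"),
                                    tornado_attribution = c("cost", "benefit")) {
  pairs_mode <- match.arg(pairs_mode)
  range_convention <- match.arg(range_convention)
  tornado_attribution <- match.arg(tornado_attribution)
  ev <- record$evidence
  if (is.null(ev))
    stop("intervention '", record$id, "' has no evidence payload ",
         "(use impute_uncertainty)", call. = FALSE)
  ju <- tryCatch(
    switch(ev$medium,
      mean_se = from_mean_se(ev$se_cost, ev$se_benefit, ev$rho, pooled_rho),
      mean_ci = from_mean_ci(ev$ci_cost, ev$ci_benefit, ev$level, ev$rho,
                             pooled_rho),
      raw_pairs = ,
      scatter_points = from_raw_pairs(ev$delta_cost, ev$delta_benefit,
                                      mode = pairs_mode),
      univariate_table = from_univariate_table(ev$rows, range_convention),
      tornado_icer = from_tornado_icer(
        base_icer = record$delta_cost_pp / record$delta_benefit_pp,
        bars = ev$bars, delta_benefit_base = record$delta_benefit_pp,
        attribution = tornado_attribution,
        range_convention = range_convention),
      icer_histogram = from_icer_histogram(
        ev$bin_edges, ev$counts, record$delta_cost_pp,
        record$delta_benefit_pp, rho_fixed = NULL, pooled_rho = pooled_rho),
      icer_cdf = from_icer_cdf(
        ev$points, record$delta_cost_pp, record$delta_benefit_pp,
        rho_fixed = NULL, pooled_rho = pooled_rho),
      ceac = from_ceac(ev$points, record$delta_cost_pp,
                       record$delta_benefit_pp),
      stop("unknown evidence medium: ", ev$medium, call. = FALSE)
    ),
    error = function(e) stop("intervention '", record$id, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ju
}

# media whose payload pins the correlation without a pooled default
medium_carries_rho <- function(ev) {
  if (is.null(ev)) return(FALSE)
  switch(ev$medium,
         mean_se = ,
         mean_ci = !is.null(ev$rho),
         raw_pairs = ,
         scatter_points = ,
         univariate_table = ,
         tornado_icer = ,
         ceac = TRUE,
         icer_histogram = ,
         icer_cdf = FALSE,
         FALSE)
}
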