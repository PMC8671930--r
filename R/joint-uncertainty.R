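#' Joint uncertainty in per-patient incremental cost and benefit
#'
#' The common currency of all reconstruction routines: the standard deviation
#' of incremental cost, the standard deviation of incremental benefit, and
#' their correlation. A bivariate normal on the incremental scale is the
#' default family; when raw simulations are available the empirical pairs can
#' be retained instead and resampled.
#'
#' @param sd_cost Standard deviation of incremental cost per patient
#'   (currency), \eqn{\sigma_C \ge 0}.
#' @param sd_benefit Standard deviation of incremental benefit per patient
#'   (DALYs), \eqn{\sigma_E \ge 0}.
#' @param correlation Correlation \eqn{\rho \in [-1, 1]} between incremental
#'   cost and incremental benefit.
#' @param family `"bivariate_normal"` or `"empirical"`.
#' @param sample For the empirical family, a data frame with columns
#'   `delta_cost`, `delta_benefit` holding the retained pairs.
#' @param provenance `"reconstructed"` (from this intervention's own
#'   sensitivity analysis) or `"imputed"` (pooled from the informed set).
#' @param diagnostics Optional character vector of warnings accumulated
#'   during reconstruction (degenerate margins, asymmetric intervals, large
#'   fit residuals).
#' @param fit_residual Optional numeric residual of a distribution fit
#'   (ICER histogram/CDF and CEAC inversions).
#'
#' @return An object of class `"joint_uncertainty"`.
#' @export
joint_uncertainty <- function(sd_cost, sd_benefit, correlation,
                              family = c("bivariate_normal", "empirical"),
                              sample = NULL,
                              provenance = c("reconstructed", "imputed"),
                              diagnostics = character(),
                              fit_residual = NA_real_) {
  family <- match.arg(family)
  provenance <- match.arg(provenance)
  sd_cost <- unname(sd_cost); sd_benefit <- unname(sd_benefit)
  correlation <- unname(correlation)
  stopifnot(is.finite(sd_cost), is.finite(sd_benefit), is.finite(correlation))
  if (sd_cost < 0 || sd_benefit < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (correlation < -1 || correlation > 1)
    stop("correlation must lie in [-1, 1]", call. = FALSE)
  if (family == "empirical" && is.null(sample))
    stop("empirical family requires the retained sample", call. = FALSE)
  if (family == "bivariate_normal" && !is.null(sample))
    stop("sample is only kept for the empirical family", call. = FALSE)
  structure(
    list(sd_cost = sd_cost, sd_benefit = sd_benefit,
         correlation = correlation, family = family, sample = sample,
         provenance = provenance, diagnostics = diagnostics,
         fit_residual = fit_residual),
    class = "joint_uncertainty"
  )
}

#' @export
print.joint_uncertainty <- function(x, ...) {
  cat(sprintf("Joint uncertainty (%s, %s)\n", x$family, x$provenance))
  cat(sprintf("  sd(cost) = %.6g, sd(benefit) = %.6g, correlation = %.4f\n",
              x$sd_cost, x$sd_benefit, x$correlation))
  if (!is.null(x$sample))
    cat(sprintf("  empirical sample of %d pairs retained\n", nrow(x$sample)))
  if (is.finite(x$fit_residual))
    cat(sprintf("  fit residual: %.3g\n", x$fit_residual))
  for (d in x$diagnostics) cat("  note: ", d, "\n", sep = "")
  invisible(x)
}
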