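#' Pool uncertainty across informed interventions
#'
#' Averages the reconstructed standard deviations, correlations and
#' coefficients of variation across the interventions whose own sensitivity
#' analyses were available. These pooled values stand in for the missing
#' uncertainty of uninformed interventions in the exploratory analysis.
#'
#' Entries with a degenerate margin (zero standard deviation) contribute to
#' the standard-deviation averages but are excluded from the corresponding
#' coefficient-of-variation average, as are entries whose point-estimate mean
#' is zero.
#'
#' @param jus List of [joint_uncertainty()] objects.
#' @param mean_costs,mean_benefits Numeric vectors of the matching
#'   point-estimate means (same length as `jus`), used for the CV averages.
#' @return An object of class `"pooled_uncertainty"`: list with
#'   `mean_correlation`, `mean_sd_cost`, `mean_sd_benefit`, `mean_cv_cost`,
#'   `mean_cv_benefit`, `n_contributing`.
#' @export
pool_uncertainty <- function(jus, mean_costs, mean_benefits) {
  if (length(jus) < 1L)
    stop("cannot pool: no reconstructed interventions available",
         call. = FALSE)
  stopifnot(length(mean_costs) == length(jus),
            length(mean_benefits) == length(jus))
  sd_c <- vapply(jus, `[[`, numeric(1), "sd_cost")
  sd_e <- vapply(jus, `[[`, numeric(1), "sd_benefit")
  rho <- vapply(jus, `[[`, numeric(1), "correlation")
  cv_c <- ifelse(sd_c > 0 & abs(mean_costs) > 0, sd_c / abs(mean_costs), NA)
  cv_e <- ifelse(sd_e > 0 & abs(mean_benefits) > 0,
                 sd_e / abs(mean_benefits), NA)
  structure(
    list(mean_correlation = mean(rho),
         mean_sd_cost = mean(sd_c),
         mean_sd_benefit = mean(sd_e),
         mean_cv_cost = if (all(is.na(cv_c))) NA_real_
                        else mean(cv_c, na.rm = TRUE),
         mean_cv_benefit = if (all(is.na(cv_e))) NA_real_
                           else mean(cv_e, na.rm = TRUE),
         n_contributing = length(jus)),
    class = "pooled_uncertainty"
  )
}

#' @export
print.pooled_uncertainty <- function(x, ...) {
  cat(sprintf("Pooled uncertainty over %d intervention(s)\n",
              x$n_contributing))
  cat(sprintf("  mean sd(cost) = %.6g, mean sd(benefit) = %.6g\n",
              x$mean_sd_cost, x$mean_sd_benefit))
  cat(sprintf("  mean correlation = %.4f; mean CVs = %.4g (cost), %.4g (benefit)\n",
              x$mean_correlation, x$mean_cv_cost, x$mean_cv_benefit))
  invisible(x)
}

#' Impute joint uncertainty for an uninformed intervention
#'
#' Exploratory analysis for interventions whose source studies reported no
#' sensitivity analysis: their uncertainty is assumed equal to the average of
#' the values extracted from the informed set. `mode = "absolute"` copies the
#' pooled standard deviations directly; `mode = "relative"` rescales the
#' pooled coefficients of variation by the intervention's own point
#' estimates, which is preferable when cost scales differ widely across the
#' evidence base. Results carry `provenance = "imputed"` and are flagged in
#' every downstream output.
#'
#' @param record An [intervention()] with no evidence payload.
#' @param pooled A [pool_uncertainty()] result.
#' @param mode `"absolute"` or `"relative"`.
#' @return A [joint_uncertainty()] with `provenance = "imputed"`.
#' @export
impute_uncertainty <- function(record, pooled,
                               mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pooled, "pooled_uncertainty"))
  if (!is.null(record$evidence))
    stop("intervention '", record$id,
         "' has its own evidence; imputation not applicable", call. = FALSE)
  if (pooled$n_contributing < 1L)
    stop("cannot impute: pooled set is empty", call. = FALSE)
  diags <- character()
  if (mode == "absolute") {
    sd_c <- pooled$mean_sd_cost
    sd_e <- pooled$mean_sd_benefit
  } else {
    if (!is.finite(pooled$mean_cv_cost) || !is.finite(pooled$mean_cv_benefit))
      stop("cannot impute in relative mode: pooled CVs unavailable",
           call. = FALSE)
    if (record$delta_cost_pp == 0 || record$delta_benefit_pp == 0)
      diags <- c(diags, "zero point estimate: relative imputation degenerate")
    sd_c <- pooled$mean_cv_cost * abs(record$delta_cost_pp)
    sd_e <- pooled$mean_cv_benefit * abs(record$delta_benefit_pp)
  }
  rho <- pooled$mean_correlation
  if (sd_c == 0 || sd_e == 0) rho <- 0
  joint_uncertainty(sd_c, sd_e, rho, provenance = "imputed",
                    diagnostics = diags)
}
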