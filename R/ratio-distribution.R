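# Distribution of the ICER, the ratio dC/dE of two correlated normal
# margins. Used to invert ICER histograms and cumulative distributions back
# to (sd_cost, sd_benefit).

#' CDF of the ratio of two correlated normal variables
#'
#' Computes `P(C / E <= t)` where `(C, E)` is bivariate normal with means
#' `(mean_cost, mean_benefit)`, standard deviations `(sd_cost, sd_benefit)`
#' and correlation `rho`. The event is split on the sign of the denominator:
#' `P(C - tE <= 0, E > 0) + P(C - tE >= 0, E < 0)`, each term a rectangle
#' probability of a bivariate normal. The ratio of normals has no moments,
#' but its CDF is well defined everywhere.
#'
#' @param t Numeric vector of ratio values (currency per DALY).
#' @param mean_cost,mean_benefit Means of the numerator and denominator.
#' @param sd_cost,sd_benefit Standard deviations (either may be zero).
#' @param rho Correlation in `[-1, 1]`.
#' @return Vector of probabilities, same length as `t`.
#' @export
picer <- function(t, mean_cost, mean_benefit, sd_cost, sd_benefit, rho = 0) {
  stopifnot(sd_cost >= 0, sd_benefit >= 0, abs(rho) <= 1)
  vapply(t, picer1, numeric(1), mean_cost = mean_cost,
         mean_benefit = mean_benefit, sd_cost = sd_cost,
         sd_benefit = sd_benefit, rho = rho)
}

picer1 <- function(t, mean_cost, mean_benefit, sd_cost, sd_benefit, rho) {
  if (sd_benefit == 0) {
    # denominator degenerate at mean_benefit (must be nonzero upstream)
    if (mean_benefit > 0) {
      if (sd_cost == 0) return(as.numeric(mean_cost / mean_benefit <= t))
      return(stats::pnorm(t * mean_benefit, mean_cost, sd_cost))
    }
    if (sd_cost == 0) return(as.numeric(mean_cost / mean_benefit <= t))
    return(stats::pnorm(t * mean_benefit, mean_cost, sd_cost,
                        lower.tail = FALSE))
  }
  if (sd_cost == 0) {
    # C fixed: C/E <= t  <=>  (E >= C/t or E < 0 side), handle via D = C - tE
    mu_d <- mean_cost - t * mean_benefit
    sd_d <- abs(t) * sd_benefit
    if (sd_d == 0) {
      p1 <- as.numeric(mu_d <= 0) * stats::pnorm(0, mean_benefit, sd_benefit,
                                                 lower.tail = FALSE)
      p2 <- as.numeric(mu_d >= 0) * stats::pnorm(0, mean_benefit, sd_benefit)
      return(p1 + p2)
    }
    # D and E are perfectly (anti)correlated; P(D<=0, E>0) via interval on E
    # D = mean_cost - tE: D<=0 <=> tE >= mean_cost
    if (t > 0) {
      p1 <- stats::pnorm(max(0, mean_cost / t), mean_benefit, sd_benefit,
                         lower.tail = FALSE)
      p2 <- stats::pnorm(min(0, mean_cost / t), mean_benefit, sd_benefit)
    } else if (t < 0) {
      p1 <- stats::pnorm(0, mean_benefit, sd_benefit, lower.tail = FALSE) -
        stats::pnorm(max(0, mean_cost / t), mean_benefit, sd_benefit,
                     lower.tail = FALSE)
      p2 <- stats::pnorm(0, mean_benefit, sd_benefit) -
        stats::pnorm(min(0, mean_cost / t), mean_benefit, sd_benefit)
    } else { # t == 0: P(C <= 0) with C fixed
      return(as.numeric(mean_cost <= 0))
    }
    return(max(0, p1) + max(0, p2))
  }
  # general case: D = C - tE jointly normal with E
  mu <- c(mean_cost - t * mean_benefit, mean_benefit)
  var_d <- sd_cost^2 - 2 * t * rho * sd_cost * sd_benefit + t^2 * sd_benefit^2
  var_d <- max(var_d, 0)
  cov_de <- rho * sd_cost * sd_benefit - t * sd_benefit^2
  sigma <- matrix(c(var_d, cov_de, cov_de, sd_benefit^2), 2L)
  # guard against numerically indefinite matrices at |rho| ~ 1
  eig <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (eig < 0) sigma <- sigma + diag(2) * (abs(eig) + 1e-12)
  p1 <- mvtnorm::pmvnorm(lower = c(-Inf, 0), upper = c(0, Inf),
                         mean = mu, sigma = sigma)
  p2 <- mvtnorm::pmvnorm(lower = c(0, -Inf), upper = c(Inf, 0),
                         mean = mu, sigma = sigma)
  min(1, max(0, as.numeric(p1) + as.numeric(p2)))
}
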