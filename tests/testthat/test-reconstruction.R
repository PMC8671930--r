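# Inverting each sensitivity-analysis medium back to joint uncertainty.

test_that("standard errors map through unchanged, with pooled-rho fallback", {
  ju <- from_mean_se(30, 0.2, rho = 0)
  expect_equal(c(ju$sd_cost, ju$sd_benefit, ju$correlation), c(30, 0.2, 0))
  ju <- from_mean_se(30, 0.2, rho = NULL, pooled_rho = 0.25)
  expect_equal(ju$correlation, 0.25)
  ju <- from_mean_se(0, 0, rho = 0)
  expect_equal(c(ju$sd_cost, ju$sd_benefit), c(0, 0))
  expect_error(from_mean_se(-1, 0.2), "non-negative")
})

test_that("confidence intervals invert through the normal quantile", {
  ju <- from_mean_ci(c(40, 160), c(0.5, 1.5), level = 0.95, rho = 0)
  expect_equal(ju$sd_cost, 120 / (2 * qnorm(0.975)), tolerance = 1e-12)
  expect_equal(ju$sd_cost, 30.6126, tolerance = 1e-4)
  # zero-width interval is a degenerate margin
  ju <- from_mean_ci(c(40, 160), c(1, 1), level = 0.95, rho = 0.4)
  expect_equal(ju$sd_benefit, 0)
  expect_equal(ju$correlation, 0)
  # interquartile-style level
  ju <- from_mean_ci(c(-1, 1), c(0, 1), level = 0.50, rho = 0)
  expect_equal(ju$sd_cost, 1 / qnorm(0.75), tolerance = 1e-12)
  expect_equal(ju$sd_cost, 1.4826, tolerance = 1e-4)
  expect_error(from_mean_ci(c(2, 1), c(0, 1)), "lower <= upper")
  # agreement contract with the SE medium at matching width
  se <- diff(c(40, 160)) / (2 * qnorm(0.975))
  expect_equal(from_mean_se(se, 0.1, rho = 0)$sd_cost,
               from_mean_ci(c(40, 160), c(0, 0.2), rho = 0)$sd_cost)
})

test_that("raw pairs are summarised by their sample moments", {
  ju <- from_raw_pairs(c(0, 2, 4), c(0, 1, 2))
  expect_equal(c(ju$sd_cost, ju$sd_benefit, ju$correlation), c(2, 1, 1))
  # forward-simulation recovery at n = 10^4
  d <- rbvn(1e4, 100, 1, 50, 0.5, -0.3, seed = 11)
  ju <- from_raw_pairs(d$delta_cost, d$delta_benefit)
  expect_equal(ju$sd_cost, 50, tolerance = 0.05)
  expect_equal(ju$sd_benefit, 0.5, tolerance = 0.05)
  expect_lt(abs(ju$correlation - (-0.3)), 0.03)  # ~3 sampling SEs at n=1e4
  # degenerate margin
  expect_warning(ju <- from_raw_pairs(c(1, 2, 3), c(1, 1, 1)),
                 "zero variance")
  expect_equal(c(ju$sd_benefit, ju$correlation), c(0, 0))
  expect_error(from_raw_pairs(1:2, 1:2), "at least 3")
  # empirical mode keeps the pairs
  ju <- from_raw_pairs(d$delta_cost, d$delta_benefit, mode = "empirical")
  expect_identical(ju$family, "empirical")
  expect_identical(nrow(ju$sample), 10000L)
})

test_that("univariate tables sum independent parameter contributions", {
  one <- data.frame(param_id = "p", dc_low = 80, dc_high = 120,
                    de_low = 0.9, de_high = 1.1)
  ju <- from_univariate_table(one, "extremes_uniform")
  expect_equal(ju$sd_cost, 40 / sqrt(12), tolerance = 1e-12)
  expect_equal(ju$sd_benefit, 0.2 / sqrt(12), tolerance = 1e-12)
  expect_equal(ju$correlation, 1)  # one parameter forces |rho| = 1
  # opposite co-movement flips the sign
  anti <- data.frame(param_id = "p", dc_low = 80, dc_high = 120,
                     de_low = 1.1, de_high = 0.9)
  expect_equal(from_univariate_table(anti)$correlation, -1)
  # orthogonal rows: no covariance
  two <- data.frame(param_id = c("p1", "p2"),
                    dc_low = c(80, 100), dc_high = c(120, 100),
                    de_low = c(1, 0.9), de_high = c(1, 1.1))
  ju <- from_univariate_table(two)
  expect_equal(ju$correlation, 0)
  expect_equal(ju$sd_cost, 40 / sqrt(12), tolerance = 1e-12)
  # interval95 convention divides the half-range by the 97.5% quantile
  ju <- from_univariate_table(one, "interval95")
  expect_equal(ju$sd_cost, 20 / qnorm(0.975), tolerance = 1e-12)
  expect_error(from_univariate_table(one[0, ]), "empty")
})

test_that("tornado ICER bars attribute uncertainty to one margin", {
  bars <- data.frame(param_id = "p", icer_low = 40, icer_high = 80)
  ju <- from_tornado_icer(60, bars, delta_benefit_base = 2,
                          attribution = "cost")
  expect_equal(ju$sd_cost, (40 / sqrt(12)) * 2, tolerance = 1e-12)
  expect_equal(ju$sd_cost, 23.094, tolerance = 1e-3)
  expect_equal(c(ju$sd_benefit, ju$correlation), c(0, 0))
  ju <- from_tornado_icer(60, bars, delta_benefit_base = 2,
                          attribution = "cost", range_convention = "interval95")
  expect_equal(ju$sd_cost, (20 / qnorm(0.975)) * 2, tolerance = 1e-12)
  expect_equal(ju$sd_cost, 20.41, tolerance = 1e-2)
  # zero-width bars give a point mass
  flat <- data.frame(param_id = "p", icer_low = 60, icer_high = 60)
  ju <- from_tornado_icer(60, flat, delta_benefit_base = 2)
  expect_equal(c(ju$sd_cost, ju$sd_benefit), c(0, 0))
  expect_error(from_tornado_icer(60, bars, delta_benefit_base = 0),
               "zero")
  # benefit attribution maps the ICER interval through dE = dC / ICER
  ju <- from_tornado_icer(60, bars, delta_benefit_base = 2,
                          attribution = "benefit",
                          range_convention = "interval95")
  z <- qnorm(0.975)
  sd_icer <- 20 / z
  e_ends <- sort(120 / (60 + c(-1, 1) * z * sd_icer))
  expect_equal(ju$sd_benefit, diff(e_ends) / (2 * z), tolerance = 1e-12)
  expect_equal(ju$sd_cost, 0)
})

test_that("ICER histogram inversion recovers the generating spread", {
  truth <- list(delta_cost_pp = 100, delta_benefit_pp = 1,
                sd_cost = 50, sd_benefit = 0.5, correlation = 0)
  ev <- render_payload(truth, "icer_histogram", seed = 21,
                       n_hist_draws = 1e5, n_bins = 20)
  ju <- from_icer_histogram(ev$bin_edges, ev$counts, 100, 1, rho_fixed = 0)
  expect_equal(ju$sd_cost, 50, tolerance = 0.10)
  expect_equal(ju$sd_benefit, 0.5, tolerance = 0.10)
  # all mass in one bin pins both margins near zero
  ju <- from_icer_histogram(c(99, 100, 101, 102), c(0, 500, 0), 100, 1)
  expect_lt(ju$sd_cost / 100, 0.05)
  expect_lt(ju$sd_benefit, 0.05)
  # a permuted, non-unimodal histogram fits with a loud residual
  ju <- from_icer_histogram(seq(0, 200, by = 20),
                            c(500, 10, 400, 5, 300, 10, 400, 5, 500, 300),
                            100, 1)
  expect_true(any(grepl("poor", ju$diagnostics)))
  expect_gt(ju$fit_residual, 0.01)
})

test_that("ICER CDF inversion recovers the generating spread", {
  truth <- list(delta_cost_pp = 100, delta_benefit_pp = 1,
                sd_cost = 50, sd_benefit = 0.5, correlation = 0)
  ev <- render_payload(truth, "icer_cdf")
  ju <- from_icer_cdf(ev$points, 100, 1, rho_fixed = 0)
  expect_equal(ju$sd_cost, 50, tolerance = 0.10)
  expect_equal(ju$sd_benefit, 0.5, tolerance = 0.10)
  # sparse three-quantile payload still identifies the scale
  ev3 <- render_payload(truth, "icer_cdf",
                        cdf_probs = c(0.025, 0.5, 0.975))
  ju3 <- from_icer_cdf(ev3$points, 100, 1, rho_fixed = 0)
  expect_equal(ju3$sd_cost, 50, tolerance = 0.15)
  expect_equal(ju3$sd_benefit, 0.5, tolerance = 0.15)
  # a near-step CDF collapses to a point mass
  step <- data.frame(icer = c(99.99, 100, 100.01),
                     cum_prob = c(0, 0.5, 1))
  ju <- from_icer_cdf(step, 100, 1)
  expect_lt(ju$sd_cost / 100, 0.05)
  expect_error(from_icer_cdf(data.frame(icer = 1:2, cum_prob = c(0, 1)),
                             100, 1), "at least 3")
})

test_that("histogram and CDF inversions agree on the same distribution", {
  truth <- list(delta_cost_pp = 100, delta_benefit_pp = 1,
                sd_cost = 40, sd_benefit = 0.4, correlation = 0)
  hist_ev <- render_payload(truth, "icer_histogram", seed = 33,
                            n_hist_draws = 1e5, n_bins = 20)
  cdf_ev <- render_payload(truth, "icer_cdf")
  ju_h <- from_icer_histogram(hist_ev$bin_edges, hist_ev$counts, 100, 1)
  ju_c <- from_icer_cdf(cdf_ev$points, 100, 1)
  expect_equal(ju_h$sd_cost, ju_c$sd_cost, tolerance = 0.10)
  expect_equal(ju_h$sd_benefit, ju_c$sd_benefit, tolerance = 0.15)
})

test_that("CEAC inversion recovers all three shape parameters", {
  truth <- list(delta_cost_pp = 50, delta_benefit_pp = 1,
                sd_cost = 50, sd_benefit = 0.5, correlation = 0.3)
  ev <- render_payload(truth, "ceac", wtp_grid = c(0, 61, 200))
  ju <- from_ceac(ev$points, 50, 1)
  expect_equal(ju$sd_cost, 50, tolerance = 0.05)
  expect_equal(ju$sd_benefit, 0.5, tolerance = 0.05)
  expect_equal(ju$correlation, 0.3, tolerance = 0.05)
  # at lambda = 0 the curve reads P(cost saving) = pnorm(-mean_cost / sd)
  ev <- render_payload(list(delta_cost_pp = 0, delta_benefit_pp = 1,
                            sd_cost = 40, sd_benefit = 0.4,
                            correlation = 0), "ceac")
  expect_equal(ev$points$prob_ce[ev$points$wtp == 0], 0.5)
  # a saturated curve carries no information about the scale
  flat <- data.frame(wtp = c(0, 50, 100), prob_ce = c(1, 1, 1))
  expect_error(from_ceac(flat, 50, 1), "unidentifiable")
  # inconsistent three-point curves are refused, not silently smoothed
  bad <- data.frame(wtp = c(0, 61, 200), prob_ce = c(0.9, 0.1, 0.95))
  expect_error(from_ceac(bad, 50, 1), "residual")
})

test_that("reconstruct_uncertainty dispatches on the medium", {
  iv <- make_iv("x", dc = 100, de = 1,
                evidence = evidence_mean_ci(c(40, 160), c(0.5, 1.5),
                                            rho = 0.2))
  ju <- reconstruct_uncertainty(iv)
  expect_equal(ju$sd_cost, from_mean_ci(c(40, 160), c(0.5, 1.5),
                                        rho = 0.2)$sd_cost)
  expect_identical(ju$provenance, "reconstructed")
  # raw pairs honour the configured mode
  d <- rbvn(500, 100, 1, 50, 0.5, 0, seed = 3)
  iv <- make_iv("y", evidence = evidence_raw_pairs(d$delta_cost,
                                                   d$delta_benefit))
  expect_identical(reconstruct_uncertainty(iv, pairs_mode = "empirical")$family,
                   "empirical")
  # unknown medium tag fails loudly
  iv$evidence$medium <- "telepathy"
  expect_error(reconstruct_uncertainty(iv), "unknown")
  # errors carry the intervention id
  iv2 <- make_iv("noev", evidence = NULL)
  expect_error(reconstruct_uncertainty(iv2), "noev")
})

test_that("reconstructed parameters always satisfy the constraints", {
  set.seed(7)
  for (i in 1:20) {
    sC <- runif(1, 0, 100); sE <- runif(1, 0, 1)
    rho <- runif(1, -0.9, 0.9)
    truth <- list(delta_cost_pp = runif(1, 10, 300),
                  delta_benefit_pp = runif(1, 0.5, 3),
                  sd_cost = sC, sd_benefit = sE, correlation = rho)
    medium <- sample(c("mean_se", "mean_ci", "univariate_table", "ceac"), 1)
    ev <- render_payload(truth, medium, seed = i)
    iv <- intervention(paste0("p", i), delta_cost_pp = truth$delta_cost_pp,
                       delta_benefit_pp = truth$delta_benefit_pp,
                       eligible_population = 100, coverage = 1,
                       evidence = ev)
    ju <- reconstruct_uncertainty(iv)
    expect_gte(ju$sd_cost, 0)
    expect_gte(ju$sd_benefit, 0)
    expect_true(ju$correlation >= -1 && ju$correlation <= 1)
    # closed-form media invert exactly
    if (medium %in% c("mean_se", "mean_ci", "univariate_table")) {
      expect_equal(ju$sd_cost, sC, tolerance = 1e-8)
      expect_equal(ju$sd_benefit, sE, tolerance = 1e-8)
      expect_equal(ju$correlation, rho, tolerance = 1e-6)
    }
  }
})
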