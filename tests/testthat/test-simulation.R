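# Population scaling, discounting, joint sampling and the pNHE engine.

test_that("annuity factor matches direct summation", {
  expect_identical(annuity_factor(1, 0.03), 1)
  expect_identical(annuity_factor(20, 0), 20)
  expect_equal(annuity_factor(20, 0.03), sum(1.03^(-(0:19))),
               tolerance = 1e-15)
  expect_equal(annuity_factor(20, 0.03), 15.3238, tolerance = 1e-4)
})

test_that("per-patient net health effect nets costs at the opportunity cost", {
  expect_equal(per_patient_nhe(2, 61, 61), 1)
  expect_equal(per_patient_nhe(1, 61, 61), 0)
  expect_equal(per_patient_nhe(0, 122, 61), -2)
})

test_that("population scaling is the plain product", {
  A <- annuity_factor(20, 0.03)
  expect_equal(population_scale(1, 1000, 0.5, A), 500 * A)
  expect_equal(population_scale(3.7, 10, 0, A), 0)
  expect_equal(population_scale(-2, 10, 1, 1), -20)
})

test_that("joint sampling reproduces the requested moments", {
  ju <- joint_uncertainty(50, 0.5, -0.3)
  d <- sample_joint(ju, 100, 1, 1e5, seed = 77)
  expect_equal(sd(d$delta_cost), 50, tolerance = 0.03)
  expect_equal(sd(d$delta_benefit), 0.5, tolerance = 0.03)
  expect_equal(cor(d$delta_cost, d$delta_benefit), -0.3, tolerance = 0.03)
  expect_equal(mean(d$delta_cost), 100, tolerance = 0.01)
  # point mass
  d <- sample_joint(joint_uncertainty(0, 0, 0), 61, 2, 10, seed = 1)
  expect_true(all(d$delta_cost == 61) && all(d$delta_benefit == 2))
  # determinism
  d1 <- sample_joint(ju, 100, 1, 100, seed = 5)
  d2 <- sample_joint(ju, 100, 1, 100, seed = 5)
  expect_identical(d1, d2)
  # empirical family resamples recentred pairs
  pairs <- data.frame(delta_cost = c(0, 10, 20), delta_benefit = c(1, 2, 3))
  jue <- joint_uncertainty(10, 1, 1, family = "empirical", sample = pairs)
  d <- sample_joint(jue, 100, 0, 3000, seed = 2)
  expect_true(all(d$delta_cost %in% (c(0, 10, 20) - 10 + 100)))
  expect_equal(mean(d$delta_benefit), -2 + mean(c(1, 2, 3)) + 0,
               tolerance = 0.1)
})

test_that("pNHE draws have the closed-form mean and variance", {
  ctx <- decision_context(time_horizon_years = 20, discount_rate = 0.03,
                          opportunity_cost_per_daly = 61,
                          n_simulations = 1e5, seed = 123)
  iv <- make_iv("m", dc = 100, de = 1.8, N = 1000, cov = 0.5,
                evidence = NULL)
  ju <- joint_uncertainty(50, 0.5, -0.3)
  pd <- simulate_pnhe(iv, ju, ctx)
  A <- annuity_factor(20, 0.03)
  scale <- A * 1000 * 0.5
  mu <- per_patient_nhe(1.8, 100, 61) * scale
  sigma_pp <- sqrt(0.5^2 + (50 / 61)^2 - 2 * (-0.3) * 0.5 * 50 / 61)
  se_mc <- sigma_pp * scale / sqrt(1e5)
  expect_lt(abs(mean(pd$draws) - mu), 3 * se_mc)
  expect_equal(sd(pd$draws), sigma_pp * scale, tolerance = 0.01)
  expect_identical(length(pd$draws), 100000L)
})

test_that("degenerate uncertainty collapses the draws to the point estimate", {
  ctx <- decision_context(time_horizon_years = 1, discount_rate = 0,
                          opportunity_cost_per_daly = 61,
                          n_simulations = 50, seed = 1)
  iv <- make_iv("d", dc = 61, de = 2, N = 100, cov = 1, evidence = NULL)
  pd <- simulate_pnhe(iv, joint_uncertainty(0, 0, 0), ctx)
  expect_true(all(pd$draws == 100))
})

test_that("per-intervention seeds are order-independent and stable", {
  ctx <- decision_context(n_simulations = 500, seed = 99)
  a <- make_iv("alpha"); b <- make_iv("beta")
  ju <- joint_uncertainty(10, 0.1, 0)
  d_ab <- simulate_pnhe(a, ju, ctx)$draws
  # simulate b first, then a again: a's stream is unchanged
  invisible(simulate_pnhe(b, ju, ctx))
  expect_identical(simulate_pnhe(a, ju, ctx)$draws, d_ab)
  expect_false(identical(simulate_pnhe(b, ju, ctx)$draws, d_ab))
  expect_identical(derive_seed(99, "alpha"), derive_seed(99L, "alpha"))
  expect_lt(derive_seed(99, paste(rep("x", 200), collapse = "")), 2^31)
})

test_that("rescaling all cost quantities and k reproduces draws exactly", {
  f <- 1000
  ctx1 <- decision_context(opportunity_cost_per_daly = 61,
                           n_simulations = 2000, seed = 31)
  ctx2 <- decision_context(opportunity_cost_per_daly = 61 * f,
                           n_simulations = 2000, seed = 31)
  iv1 <- make_iv("sc", dc = 75, de = 1.5, evidence = NULL)
  iv2 <- make_iv("sc", dc = 75 * f, de = 1.5, evidence = NULL)
  ju1 <- joint_uncertainty(50, 0.5, 0.25)
  ju2 <- joint_uncertainty(50 * f, 0.5, 0.25)
  expect_identical(simulate_pnhe(iv1, ju1, ctx1)$draws,
                   simulate_pnhe(iv2, ju2, ctx2)$draws)
})

test_that("simulation means respond linearly to the inputs", {
  # E[pNHE] is invariant to the correlation and scales with N * c
  ctx <- decision_context(n_simulations = 4000, seed = 8)
  ju_pos <- joint_uncertainty(30, 0.3, 0.8)
  ju_neg <- joint_uncertainty(30, 0.3, -0.8)
  iv <- make_iv("l", dc = 80, de = 1.5, N = 1000, cov = 0.5,
                evidence = NULL)
  m_pos <- mean(simulate_pnhe(iv, ju_pos, ctx)$draws)
  m_neg <- mean(simulate_pnhe(iv, ju_neg, ctx)$draws)
  expect_equal(m_pos, m_neg, tolerance = 0.05)
  iv2 <- make_iv("l", dc = 80, de = 1.5, N = 2000, cov = 0.5,
                 evidence = NULL)
  expect_equal(mean(simulate_pnhe(iv2, ju_pos, ctx)$draws), 2 * m_pos,
               tolerance = 1e-12)
})
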