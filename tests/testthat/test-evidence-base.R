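# Data model, validation and workbook round-trips.

test_that("constructors enforce the basic invariants", {
  expect_error(decision_context(time_horizon_years = 0), "time_horizon")
  expect_error(decision_context(opportunity_cost_per_daly = 0), "> 0")
  expect_error(intervention("a", delta_cost_pp = 1, delta_benefit_pp = 1,
                            eligible_population = -1, coverage = 0.5),
               "eligible_population")
  expect_error(intervention("a", delta_cost_pp = 1, delta_benefit_pp = 1,
                            eligible_population = 1, coverage = 1.3),
               "coverage")
  expect_error(evidence_mean_se(-1, 0.1), "non-negative")
  expect_error(evidence_mean_ci(c(2, 1), c(0, 1)), "lower <= upper")
  expect_error(evidence_raw_pairs(1:2, 1:2), "at least 3")
  expect_error(evidence_icer_cdf(data.frame(icer = 1:3,
                                            cum_prob = c(0.5, 0.2, 0.9))),
               "non-decreasing")
  expect_error(make_eb(list(make_iv("x"), make_iv("x"))), "duplicate")
})

test_that("validate_evidence_base reports one diagnostic per violation", {
  eb <- make_eb(list(make_iv("a"), make_iv("b"), make_iv("c")))
  expect_identical(nrow(validate_evidence_base(eb)), 0L)
  # corrupt fields past the constructors to exercise the diagnostics path
  eb$interventions$b$eligible_population <- -5
  eb$interventions$c$coverage <- 1.7
  d <- validate_evidence_base(eb)
  expect_identical(nrow(d), 2L)
  expect_setequal(d$intervention_id, c("b", "c"))
  expect_setequal(d$field, c("eligible_population", "coverage"))
})

test_that("evidence base round-trips through the CSV workbook", {
  truth <- demo_truth()[c(1, 6, 8, 11, 12, 13, 21), ]  # one row per medium
  g <- generate_evidence_base(truth,
                              context = decision_context(n_simulations = 1000,
                                                         seed = 9),
                              n_pairs = 50, n_hist_draws = 2000)
  dir <- withr::local_tempdir()
  write_evidence_base(g$evidence_base, dir)
  eb2 <- load_evidence_base(dir, format = "csv_dir")
  expect_identical(length(eb2$interventions),
                   length(g$evidence_base$interventions))
  for (id in names(g$evidence_base$interventions)) {
    a <- g$evidence_base$interventions[[id]]
    b <- eb2$interventions[[id]]
    expect_equal(a$delta_cost_pp, b$delta_cost_pp)
    expect_equal(a$delta_benefit_pp, b$delta_benefit_pp)
    expect_equal(a$eligible_population, b$eligible_population)
    expect_equal(a$coverage, b$coverage)
    expect_identical(a$evidence$medium, b$evidence$medium)
  }
  # payload content survives: a sampled medium and an exact medium
  a <- g$evidence_base$interventions[["r1"]]$evidence
  b <- eb2$interventions[["r1"]]$evidence
  expect_equal(a$delta_cost, b$delta_cost)
  a <- g$evidence_base$interventions[["c1"]]$evidence
  b <- eb2$interventions[["c1"]]$evidence
  expect_equal(a$ci_cost, b$ci_cost)
  expect_equal(a$rho, b$rho)
  expect_equal(g$evidence_base$context$opportunity_cost_per_daly,
               eb2$context$opportunity_cost_per_daly)
})

test_that("records without evidence load as absent, not as errors", {
  truth <- demo_truth()[1:2, ]
  truth$medium[2] <- "none"
  g <- generate_evidence_base(truth, context = decision_context(seed = 5))
  dir <- withr::local_tempdir()
  write_evidence_base(g$evidence_base, dir)
  eb2 <- load_evidence_base(dir)
  expect_null(eb2$interventions[[2]]$evidence)
  expect_s3_class(eb2$interventions[[1]]$evidence, "sa_evidence")
})

test_that("schema violations fail with the sheet and column named", {
  g <- generate_evidence_base(demo_truth()[1:3, ],
                              context = decision_context(seed = 2))
  dir <- withr::local_tempdir()
  write_evidence_base(g$evidence_base, dir)
  # out-of-range coverage caught at load
  iv <- utils::read.csv(file.path(dir, "interventions.csv"))
  iv$coverage[1] <- 1.3
  utils::write.csv(iv, file.path(dir, "interventions.csv"),
                   row.names = FALSE)
  expect_error(load_evidence_base(dir), "coverage")
  # missing required column
  iv$coverage <- NULL
  utils::write.csv(iv, file.path(dir, "interventions.csv"),
                   row.names = FALSE)
  expect_error(load_evidence_base(dir), "coverage")
  # missing required sheet
  file.remove(file.path(dir, "globals.csv"))
  expect_error(load_evidence_base(dir), "globals")
})

test_that("duplicate ids and non-numeric cells are rejected at load", {
  g <- generate_evidence_base(demo_truth()[1:2, ],
                              context = decision_context(seed = 2))
  dir <- withr::local_tempdir()
  write_evidence_base(g$evidence_base, dir)
  iv <- utils::read.csv(file.path(dir, "interventions.csv"),
                        stringsAsFactors = FALSE)
  iv$intervention_id[2] <- iv$intervention_id[1]
  utils::write.csv(iv, file.path(dir, "interventions.csv"),
                   row.names = FALSE)
  expect_error(load_evidence_base(dir), "duplicate")
  iv <- utils::read.csv(file.path(dir, "interventions.csv"),
                        stringsAsFactors = FALSE)
  iv$intervention_id[2] <- "zz"
  iv$delta_cost_pp <- as.character(iv$delta_cost_pp)
  iv$delta_cost_pp[2] <- "oops"
  utils::write.csv(iv, file.path(dir, "interventions.csv"),
                   row.names = FALSE)
  expect_error(load_evidence_base(dir), "non-numeric")
})

test_that("write_results emits three stable, reproducible tables", {
  eb <- make_eb(list(make_iv("b", dc = 40, de = 1.5),
                     make_iv("a", dc = 61, de = 2)))
  fit <- voi_hbp(eb)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_results(fit, d1)
  expect_setequal(basename(unname(p1[1:3])),
                  c("ranking_by_population_benefit.csv",
                    "ranking_by_pnhe.csv", "research_value.csv"))
  for (p in p1[1:3]) expect_identical(nrow(utils::read.csv(p)), 2L)
  # determinism: a re-run with the same inputs is byte-identical
  fit2 <- voi_hbp(make_eb(list(make_iv("b", dc = 40, de = 1.5),
                               make_iv("a", dc = 61, de = 2))))
  p2 <- write_results(fit2, d2)
  for (f in c("ranking_by_pnhe.csv", "research_value.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # equal-EVPI rows sort by id, none dropped
  rv <- utils::read.csv(file.path(d1, "research_value.csv"))
  expect_setequal(rv$intervention_id, c("a", "b"))
})
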