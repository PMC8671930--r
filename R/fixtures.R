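#' @title Synthetic evidence bases with known ground truth
#'
#' @description
#' The evidence workbooks this package is designed for are typically
#' proprietary collations of published studies, so testing and demonstration
#' rely on synthetic evidence bases generated from a known bivariate-normal
#' ground truth: for each intervention a true `(sd_cost, sd_benefit,
#' correlation)` is fixed, a sensitivity-analysis payload in one of the
#' reporting media is rendered from it, and the reconstruction can then be
#' checked against the truth.
#'
#' @name fixtures
NULL

#' Render a sensitivity-analysis payload from ground truth
#'
#' Produces a payload whose generating distribution is the bivariate normal
#' defined by `truth`. Summary media (`mean_se`, `mean_ci`) are computed
#' exactly; sampled media (`raw_pairs`, `scatter_points`, `icer_histogram`)
#' are simulated under `seed`; `univariate_table` decomposes the covariance
#' into `n_params` orthogonal parameter effects whose summed contributions
#' reproduce the truth exactly; `tornado_icer` uses the cost-attributed
#' convention (the truth must have `sd_benefit = 0`); `icer_cdf` and `ceac`
#' are evaluated exactly from the ratio CDF ([picer()]) and the acceptability
#' formula respectively.
#'
#' @param truth List or one-row data frame with `delta_cost_pp`,
#'   `delta_benefit_pp`, `sd_cost`, `sd_benefit`, `correlation`.
#' @param medium One of the nine recognised media.
#' @param seed Integer seed for the sampled media.
#' @param n_pairs Draws rendered for `raw_pairs` / `scatter_points`.
#' @param n_hist_draws Internal draws behind the histogram.
#' @param n_bins Histogram bins (placed between the 0.5% and 99.5%
#'   quantiles of the simulated ICERs).
#' @param n_params Parameter rows for `univariate_table` (>= 2 unless
#'   `|correlation| = 1`) and bars for `tornado_icer`.
#' @param include_rho Attach the true correlation to `mean_se` / `mean_ci`
#'   payloads (when `FALSE` the loader substitutes the pooled default).
#' @param level Interval level for `mean_ci`.
#' @param wtp_grid Willingness-to-pay grid for `ceac`.
#' @param cdf_probs Target probabilities at which `icer_cdf` points are
#'   placed.
#' @return An [sa_evidence] payload.
#' @export
render_payload <- function(truth, medium, seed = 1L,
                           n_pairs = 10000L, n_hist_draws = 100000L,
                           n_bins = 20L, n_params = 2L,
                           include_rho = TRUE, level = 0.95,
                           wtp_grid = c(0, 30, 61, 120, 250, 500),
                           cdf_probs = seq(0.05, 0.95, by = 0.1)) {
  truth <- as.list(truth)
  dc <- truth$delta_cost_pp; de <- truth$delta_benefit_pp
  sC <- truth$sd_cost; sE <- truth$sd_benefit; rho <- truth$correlation
  stopifnot(sC >= 0, sE >= 0, abs(rho) <= 1)
  ju <- joint_uncertainty(sC, sE, if (sC == 0 || sE == 0) 0 else rho)
  switch(medium,
    mean_se = evidence_mean_se(sC, sE,
                               rho = if (include_rho) rho else NULL),
    mean_ci = {
      zq <- stats::qnorm((1 + level) / 2)
      evidence_mean_ci(dc + c(-1, 1) * zq * sC, de + c(-1, 1) * zq * sE,
                       level = level,
                       rho = if (include_rho) rho else NULL)
    },
    raw_pairs = ,
    scatter_points = {
      pairs <- sample_joint(ju, dc, de, n_pairs, seed)
      if (medium == "raw_pairs")
        evidence_raw_pairs(pairs$delta_cost, pairs$delta_benefit)
      else evidence_scatter_points(pairs$delta_cost, pairs$delta_benefit)
    },
    univariate_table = {
      if (n_params < 2L && abs(rho) < 1 && sC > 0 && sE > 0)
        stop("a univariate table with 1 parameter can only represent ",
             "|correlation| = 1; use n_params >= 2", call. = FALSE)
      # orthogonal decomposition: cost loads on parameter 1 only; benefit
      # splits between parameters 1 and 2 according to the correlation
      w <- sqrt(12)   # extremes_uniform: sd = width / sqrt(12)
      xs <- c(w * sC, rep(0, max(0, n_params - 1L)))
      ys <- c(w * sE * rho, w * sE * sqrt(max(0, 1 - rho^2)),
              rep(0, max(0, n_params - 2L)))
      ys <- ys[seq_len(max(n_params, 1L))]
      if (n_params == 1L) ys <- w * sE * sign(rho)
      rows <- data.frame(
        param_id = paste0("p", seq_len(max(n_params, 1L))),
        dc_low = dc - xs / 2, dc_high = dc + xs / 2,
        de_low = de - ys / 2, de_high = de + ys / 2)
      evidence_univariate_table(rows)
    },
    tornado_icer = {
      if (sE != 0)
        stop("the tornado-of-ICERs medium carries no benefit-margin ",
             "information; render it from a truth with sd_benefit = 0",
             call. = FALSE)
      if (de == 0) stop("ICER undefined: delta_benefit_pp = 0",
                        call. = FALSE)
      base <- dc / de
      sd_icer <- sC / abs(de)
      width <- sqrt(12) * sd_icer / sqrt(n_params)  # equal-width bars
      evidence_tornado_icer(data.frame(
        param_id = paste0("p", seq_len(n_params)),
        icer_low = base - width / 2, icer_high = base + width / 2))
    },
    icer_histogram = {
      pairs <- sample_joint(ju, dc, de, n_hist_draws, seed)
      icer <- pairs$delta_cost / pairs$delta_benefit
      qs <- stats::quantile(icer, c(0.005, 0.995), names = FALSE)
      edges <- seq(qs[1], qs[2], length.out = n_bins + 1L)
      counts <- as.numeric(graphics::hist(icer[icer >= qs[1] & icer <= qs[2]],
                                          breaks = edges, plot = FALSE)$counts)
      evidence_icer_histogram(edges, counts)
    },
    icer_cdf = {
      if (de == 0) stop("ICER undefined: delta_benefit_pp = 0",
                        call. = FALSE)
      # place points at the target probabilities by numeric inversion
      base <- dc / de
      spread <- abs(base) * sqrt((sC / max(abs(dc), 1e-12))^2 +
                                 (sE / abs(de))^2) + 1e-9
      ts <- vapply(cdf_probs, function(p) {
        stats::uniroot(function(t)
          picer(t, dc, de, sC, sE, rho) - p,
          interval = base + c(-50, 50) * spread, extendInt = "yes",
          tol = 1e-9)$root
      }, numeric(1))
      evidence_icer_cdf(data.frame(
        icer = ts, cum_prob = picer(ts, dc, de, sC, sE, rho)))
    },
    ceac = {
      m <- wtp_grid * de - dc
      s <- sqrt(pmax(wtp_grid^2 * sE^2 - 2 * wtp_grid * rho * sE * sC + sC^2,
                     1e-300))
      evidence_ceac(data.frame(wtp = wtp_grid,
                               prob_ce = stats::pnorm(m / s)))
    },
    stop("unknown medium: ", medium, call. = FALSE)
  )
}

#' Ground-truth table of the 21-intervention demonstration fixture
#'
#' A synthetic evidence base spanning the reporting-media mix observed in
#' practice (5 univariate tables, 2 tornado plots, 2 raw simulation sets,
#' 1 scatterplot, 1 ICER histogram, 1 ICER CDF, 8 confidence intervals,
#' 1 standard error) and the four qualitative decision regimes: clearly
#' cost-effective, clearly not, uncertain-include and uncertain-exclude
#' (per-patient net-benefit z-scores above 3, below -3, and inside
#' (-1.96, 1.96) respectively, at an opportunity cost of 61 per DALY).
#' Tornado truths carry no benefit-margin spread; histogram/CDF truths use
#' zero correlation; the remaining correlations are balanced so their
#' average is zero. One intervention combines a large gross population
#' health benefit with a clearly negative net effect, so the benefit and
#' pNHE rankings disagree.
#'
#' @return Data frame with columns `intervention_id`, `name`,
#'   `delta_cost_pp`, `delta_benefit_pp`, `eligible_population`, `coverage`,
#'   `sd_cost`, `sd_benefit`, `correlation`, `medium`, `regime`.
#' @export
demo_truth <- function() {
  tab <- read.csv(textConnection(
"intervention_id,delta_cost_pp,delta_benefit_pp,sd_cost,sd_benefit,correlation,medium,regime,eligible_population,coverage
u1,30,2.0,20,0.30,0.4,univariate_table,clear_include,120000,0.7
u2,100,1.8,60,0.80,-0.4,univariate_table,uncertain_include,80000,0.6
u3,50,0.5,40,0.45,0.5,univariate_table,uncertain_exclude,150000,0.5
u4,400,2.5,50,0.40,-0.5,univariate_table,clear_exclude,60000,0.8
u5,80,0.8,35,0.25,0.0,univariate_table,uncertain_exclude,90000,0.4
t1,45,1.5,30,0.00,0.0,tornado_icer,uncertain_include,70000,0.6
t2,250,1.0,50,0.00,0.0,tornado_icer,clear_exclude,40000,0.7
r1,60,1.2,50,0.50,0.3,raw_pairs,uncertain_include,100000,0.5
r2,60,2.5,20,0.20,-0.3,raw_pairs,clear_include,130000,0.8
s1,70,1.0,30,0.35,0.0,scatter_points,uncertain_exclude,50000,0.6
h1,100,1.0,50,0.50,0.0,icer_histogram,uncertain_exclude,110000,0.5
d1,60,1.3,40,0.45,0.0,icer_cdf,uncertain_include,95000,0.6
c1,25,1.6,15,0.20,0.3,mean_ci,clear_include,140000,0.7
c2,350,1.0,70,0.50,-0.3,mean_ci,clear_exclude,30000,0.8
c3,40,0.9,25,0.30,0.2,mean_ci,uncertain_include,85000,0.5
c4,2000,10.0,300,2.00,-0.2,mean_ci,clear_exclude,200000,0.9
c5,35,1.4,15,0.15,0.5,mean_ci,clear_include,75000,0.6
c6,250,6.0,25,0.30,-0.5,mean_ci,clear_include,25000,0.7
c7,90,1.4,55,0.55,0.1,mean_ci,uncertain_exclude,65000,0.5
c8,500,2.0,100,0.80,-0.1,mean_ci,clear_exclude,45000,0.6
e1,55,1.3,35,0.40,0.0,mean_se,uncertain_include,105000,0.5"),
    stringsAsFactors = FALSE)
  tab$name <- paste0("synthetic intervention ", tab$intervention_id)
  tab
}

#' Generate a synthetic evidence base with known ground truth
#'
#' Renders one payload per intervention from the truth table, assembles the
#' evidence base, and (optionally) writes it to disk in the CSV-directory
#' workbook format alongside a `truth.csv` enabling recovery tests.
#' Deterministic given `seed`.
#'
#' @param truth Truth table as returned by [demo_truth()] (the default);
#'   `medium = "none"` rows are included without evidence (exploratory
#'   cases).
#' @param context A [decision_context()]; its seed is overridden by `seed`.
#' @param seed Master seed for the sampled payload media.
#' @param dir Optional output directory for the workbook and truth table.
#' @param ... Render-size arguments passed to [render_payload()].
#' @return List with elements `evidence_base`, `truth` and (when written)
#'   `dir`; invisibly.
#' @export
generate_evidence_base <- function(truth = demo_truth(),
                                   context = decision_context(),
                                   seed = context$seed, dir = NULL, ...) {
  truth <- as.data.frame(truth)
  context$seed <- as.integer(seed)
  interventions <- lapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    ev <- if (identical(row$medium, "none")) NULL
    else render_payload(row, row$medium,
                        seed = derive_seed(seed, row$intervention_id), ...)
    intervention(row$intervention_id,
                 name = if ("name" %in% names(truth)) row$name
                        else row$intervention_id,
                 delta_cost_pp = row$delta_cost_pp,
                 delta_benefit_pp = row$delta_benefit_pp,
                 eligible_population = row$eligible_population,
                 coverage = row$coverage, evidence = ev)
  })
  eb <- evidence_base(context, interventions)
  out <- list(evidence_base = eb, truth = truth)
  if (!is.null(dir)) {
    write_evidence_base(eb, dir)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    out$dir <- dir
  }
  invisible(out)
}
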