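#' @title Evidence-base workbook input and results output
#'
#' @description
#' The evidence base travels as a small workbook with a fixed schema: one
#' `globals` table, one `interventions` table, and one payload table per
#' sensitivity-analysis medium, keyed by `intervention_id`. Two physical
#' formats are supported: a directory of CSV files named after the sheets
#' (the reference format, written by [write_evidence_base()]), or an XLSX
#' workbook with identically named sheets (read via the readxl package when
#' installed). Sheets:
#'
#' | sheet | columns |
#' |---|---|
#' | `globals` | `time_horizon_years, discount_rate, opportunity_cost_per_daly` (+ optional `benefit_discount_rate, n_simulations, seed, interval_level`) |
#' | `interventions` | `intervention_id, name, delta_cost_pp, delta_benefit_pp, eligible_population, coverage, medium` |
#' | `payload_mean_se` | `intervention_id, se_cost, se_benefit, rho` |
#' | `payload_mean_ci` | `intervention_id, ci_cost_lower, ci_cost_upper, ci_benefit_lower, ci_benefit_upper, level, rho` |
#' | `payload_pairs` | `intervention_id, delta_cost, delta_benefit` (long; serves `raw_pairs` and `scatter_points`) |
#' | `payload_univariate` | `intervention_id, param_id, dc_low, dc_high, de_low, de_high` |
#' | `payload_tornado_icer` | `intervention_id, param_id, icer_low, icer_high` |
#' | `payload_icer_histogram` | `intervention_id, bin_lower, bin_upper, count` (contiguous ascending bins) |
#' | `payload_icer_cdf` | `intervention_id, icer, cum_prob` |
#' | `payload_ceac` | `intervention_id, wtp, prob_ce` |
#'
#' `medium` is one of the nine recognised media or `none` (empty also read as
#' `none`) for interventions without sensitivity-analysis data. `rho` may be
#' left blank (`NA`) to request the pooled default. Missing payload sheets
#' are treated as empty.
#'
#' @name workbook
NULL

payload_sheets <- c("payload_mean_se", "payload_mean_ci", "payload_pairs",
                    "payload_univariate", "payload_tornado_icer",
                    "payload_icer_histogram", "payload_icer_cdf",
                    "payload_ceac")

read_sheet_csv <- function(dir, sheet, required = TRUE) {
  path <- file.path(dir, paste0(sheet, ".csv"))
  if (!file.exists(path)) {
    if (required)
      stop("missing required sheet '", sheet, "' (expected file ", path, ")",
           call. = FALSE)
    return(NULL)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

read_sheet_xlsx <- function(path, sheet, sheets, required = TRUE) {
  if (!sheet %in% sheets) {
    if (required)
      stop("missing required sheet '", sheet, "' in workbook ", path,
           call. = FALSE)
    return(NULL)
  }
  as.data.frame(readxl::read_excel(path, sheet = sheet))
}

need_cols <- function(df, sheet, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop("sheet '", sheet, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cl in setdiff(cols, c("intervention_id", "name", "param_id",
                             "medium"))) {
    v <- df[[cl]]
    if (!is.numeric(v) && !all(is.na(v))) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("sheet '", sheet, "', column '", cl, "': non-numeric value in ",
           "row(s) ", paste(utils::head(bad, 3), collapse = ", "),
           call. = FALSE)
    }
    df[[cl]] <- as.numeric(v)
  }
  df
}

opt_num <- function(df, col, default) {
  if (col %in% names(df) && length(df[[col]]) >= 1 && !is.na(df[[col]][1]))
    as.numeric(df[[col]][1]) else default
}

#' Load an evidence base from a workbook
#'
#' Reads the schema described in [workbook] from either a directory of CSV
#' sheets or an XLSX workbook (format inferred from the path when
#' `format = "auto"`), validates it, and assembles an [evidence_base()].
#' Interventions whose `medium` is `none` are loaded with absent evidence —
#' a legal state handled later by the exploratory imputation, not an error.
#'
#' @param path Directory of CSV sheets, or an `.xlsx` file.
#' @param format `"auto"`, `"csv_dir"` or `"workbook"` (XLSX).
#' @return A validated [evidence_base()].
#' @export
load_evidence_base <- function(path, format = c("auto", "csv_dir",
                                                "workbook")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "csv_dir" else "workbook"
  if (format == "workbook") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX workbooks requires the readxl package; ",
           "use the CSV-directory format instead", call. = FALSE)
    if (!file.exists(path)) stop("no such workbook: ", path, call. = FALSE)
    sheets <- readxl::excel_sheets(path)
    rd <- function(sheet, required = TRUE)
      read_sheet_xlsx(path, sheet, sheets, required)
  } else {
    if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
    rd <- function(sheet, required = TRUE)
      read_sheet_csv(path, sheet, required)
  }

  globals <- need_cols(rd("globals"), "globals",
                       c("time_horizon_years", "discount_rate",
                         "opportunity_cost_per_daly"))
  if (nrow(globals) < 1) stop("sheet 'globals' is empty", call. = FALSE)
  ctx <- decision_context(
    time_horizon_years = globals$time_horizon_years[1],
    discount_rate = globals$discount_rate[1],
    opportunity_cost_per_daly = globals$opportunity_cost_per_daly[1],
    n_simulations = opt_num(globals, "n_simulations", 1e5),
    seed = opt_num(globals, "seed", 1),
    interval_level = opt_num(globals, "interval_level", 0.95),
    benefit_discount_rate = opt_num(globals, "benefit_discount_rate",
                                    globals$discount_rate[1]))

  iv_tab <- need_cols(rd("interventions"), "interventions",
                      c("intervention_id", "delta_cost_pp",
                        "delta_benefit_pp", "eligible_population",
                        "coverage"))
  if (nrow(iv_tab) < 1)
    stop("sheet 'interventions' is empty", call. = FALSE)
  iv_tab$intervention_id <- as.character(iv_tab$intervention_id)
  if (anyDuplicated(iv_tab$intervention_id))
    stop("duplicate intervention_id in 'interventions': ",
         paste(unique(iv_tab$intervention_id[
           duplicated(iv_tab$intervention_id)]), collapse = ", "),
         call. = FALSE)
  if (!"name" %in% names(iv_tab)) iv_tab$name <- iv_tab$intervention_id
  if (!"medium" %in% names(iv_tab)) iv_tab$medium <- "none"
  iv_tab$medium[is.na(iv_tab$medium) | iv_tab$medium == ""] <- "none"
  bad_medium <- setdiff(unique(iv_tab$medium), c(sa_media, "none"))
  if (length(bad_medium) > 0)
    stop("unknown evidence medium in 'interventions': ",
         paste(bad_medium, collapse = ", "), call. = FALSE)

  pay <- list(
    mean_se = rd("payload_mean_se", required = FALSE),
    mean_ci = rd("payload_mean_ci", required = FALSE),
    pairs = rd("payload_pairs", required = FALSE),
    univariate = rd("payload_univariate", required = FALSE),
    tornado = rd("payload_tornado_icer", required = FALSE),
    histogram = rd("payload_icer_histogram", required = FALSE),
    cdf = rd("payload_icer_cdf", required = FALSE),
    ceac = rd("payload_ceac", required = FALSE)
  )
  pick <- function(tab, sheet, cols, id) {
    if (is.null(tab))
      stop("intervention '", id, "' expects payload sheet '", sheet,
           "' which is absent", call. = FALSE)
    tab <- need_cols(tab, sheet, cols)
    tab$intervention_id <- as.character(tab$intervention_id)
    sub <- tab[tab$intervention_id == id, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("no payload rows for intervention '", id, "' in sheet '", sheet,
           "'", call. = FALSE)
    sub
  }
  build_evidence <- function(id, medium) {
    switch(medium,
      none = NULL,
      mean_se = {
        p <- pick(pay$mean_se, "payload_mean_se",
                  c("intervention_id", "se_cost", "se_benefit"), id)
        rho <- if ("rho" %in% names(p) && !is.na(p$rho[1])) p$rho[1] else NULL
        evidence_mean_se(p$se_cost[1], p$se_benefit[1], rho)
      },
      mean_ci = {
        p <- pick(pay$mean_ci, "payload_mean_ci",
                  c("intervention_id", "ci_cost_lower", "ci_cost_upper",
                    "ci_benefit_lower", "ci_benefit_upper"), id)
        rho <- if ("rho" %in% names(p) && !is.na(p$rho[1])) p$rho[1] else NULL
        lvl <- if ("level" %in% names(p) && !is.na(p$level[1])) p$level[1]
               else 0.95
        evidence_mean_ci(c(p$ci_cost_lower[1], p$ci_cost_upper[1]),
                         c(p$ci_benefit_lower[1], p$ci_benefit_upper[1]),
                         level = lvl, rho = rho)
      },
      raw_pairs = ,
      scatter_points = {
        p <- pick(pay$pairs, "payload_pairs",
                  c("intervention_id", "delta_cost", "delta_benefit"), id)
        if (medium == "raw_pairs")
          evidence_raw_pairs(p$delta_cost, p$delta_benefit)
        else evidence_scatter_points(p$delta_cost, p$delta_benefit)
      },
      univariate_table = {
        p <- pick(pay$univariate, "payload_univariate",
                  c("intervention_id", "param_id", "dc_low", "dc_high",
                    "de_low", "de_high"), id)
        evidence_univariate_table(p[, c("param_id", "dc_low", "dc_high",
                                        "de_low", "de_high")])
      },
      tornado_icer = {
        p <- pick(pay$tornado, "payload_tornado_icer",
                  c("intervention_id", "param_id", "icer_low", "icer_high"),
                  id)
        evidence_tornado_icer(p[, c("param_id", "icer_low", "icer_high")])
      },
      icer_histogram = {
        p <- pick(pay$histogram, "payload_icer_histogram",
                  c("intervention_id", "bin_lower", "bin_upper", "count"), id)
        p <- p[order(p$bin_lower), , drop = FALSE]
        if (nrow(p) > 1 &&
            any(abs(p$bin_upper[-nrow(p)] - p$bin_lower[-1]) >
                1e-9 * max(abs(p$bin_upper))))
          stop("intervention '", id, "': histogram bins must be contiguous",
               call. = FALSE)
        evidence_icer_histogram(c(p$bin_lower[1], p$bin_upper), p$count)
      },
      icer_cdf = {
        p <- pick(pay$cdf, "payload_icer_cdf",
                  c("intervention_id", "icer", "cum_prob"), id)
        evidence_icer_cdf(p[, c("icer", "cum_prob")])
      },
      ceac = {
        p <- pick(pay$ceac, "payload_ceac",
                  c("intervention_id", "wtp", "prob_ce"), id)
        evidence_ceac(p[, c("wtp", "prob_ce")])
      })
  }
  interventions <- lapply(seq_len(nrow(iv_tab)), function(i) {
    row <- iv_tab[i, ]
    intervention(row$intervention_id, row$name,
                 delta_cost_pp = row$delta_cost_pp,
                 delta_benefit_pp = row$delta_benefit_pp,
                 eligible_population = row$eligible_population,
                 coverage = row$coverage,
                 evidence = build_evidence(row$intervention_id, row$medium))
  })
  evidence_base(ctx, interventions)
}

#' Write the evidence base as a CSV-directory workbook
#'
#' Emits the schema described in [workbook], one CSV per sheet; only the
#' payload sheets that have rows are written. [load_evidence_base()] reads
#' the result back field-for-field.
#'
#' @param eb An [evidence_base()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evidence_base <- function(eb, dir) {
  stopifnot(inherits(eb, "evidence_base"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ctx <- eb$context
  wr <- function(df, sheet)
    utils::write.csv(df, file.path(dir, paste0(sheet, ".csv")),
                     row.names = FALSE)
  wr(data.frame(time_horizon_years = ctx$time_horizon_years,
                discount_rate = ctx$discount_rate,
                benefit_discount_rate = ctx$benefit_discount_rate,
                opportunity_cost_per_daly = ctx$opportunity_cost_per_daly,
                n_simulations = ctx$n_simulations, seed = ctx$seed,
                interval_level = ctx$interval_level), "globals")
  ivs <- eb$interventions
  wr(data.frame(
    intervention_id = vapply(ivs, `[[`, character(1), "id"),
    name = vapply(ivs, `[[`, character(1), "name"),
    delta_cost_pp = vapply(ivs, `[[`, numeric(1), "delta_cost_pp"),
    delta_benefit_pp = vapply(ivs, `[[`, numeric(1), "delta_benefit_pp"),
    eligible_population = vapply(ivs, `[[`, numeric(1),
                                 "eligible_population"),
    coverage = vapply(ivs, `[[`, numeric(1), "coverage"),
    medium = vapply(ivs, function(iv)
      if (is.null(iv$evidence)) "none" else iv$evidence$medium,
      character(1))), "interventions")
  gather <- function(fun) {
    out <- list()
    for (iv in ivs) {
      if (is.null(iv$evidence)) next
      piece <- fun(iv$id, iv$evidence)
      if (!is.null(piece)) out[[length(out) + 1L]] <- piece
    }
    if (length(out) > 0) do.call(rbind, out) else NULL
  }
  sheets <- list(
    payload_mean_se = gather(function(id, ev)
      if (ev$medium == "mean_se")
        data.frame(intervention_id = id, se_cost = ev$se_cost,
                   se_benefit = ev$se_benefit,
                   rho = if (is.null(ev$rho)) NA_real_ else ev$rho)),
    payload_mean_ci = gather(function(id, ev)
      if (ev$medium == "mean_ci")
        data.frame(intervention_id = id,
                   ci_cost_lower = ev$ci_cost[1],
                   ci_cost_upper = ev$ci_cost[2],
                   ci_benefit_lower = ev$ci_benefit[1],
                   ci_benefit_upper = ev$ci_benefit[2], level = ev$level,
                   rho = if (is.null(ev$rho)) NA_real_ else ev$rho)),
    payload_pairs = gather(function(id, ev)
      if (ev$medium %in% c("raw_pairs", "scatter_points"))
        data.frame(intervention_id = id, delta_cost = ev$delta_cost,
                   delta_benefit = ev$delta_benefit)),
    payload_univariate = gather(function(id, ev)
      if (ev$medium == "univariate_table")
        cbind(intervention_id = id, ev$rows)),
    payload_tornado_icer = gather(function(id, ev)
      if (ev$medium == "tornado_icer")
        cbind(intervention_id = id, ev$bars)),
    payload_icer_histogram = gather(function(id, ev)
      if (ev$medium == "icer_histogram")
        data.frame(intervention_id = id,
                   bin_lower = ev$bin_edges[-length(ev$bin_edges)],
                   bin_upper = ev$bin_edges[-1], count = ev$counts)),
    payload_icer_cdf = gather(function(id, ev)
      if (ev$medium == "icer_cdf")
        data.frame(intervention_id = id, icer = ev$points$icer,
                   cum_prob = ev$points$cum_prob)),
    payload_ceac = gather(function(id, ev)
      if (ev$medium == "ceac")
        data.frame(intervention_id = id, wtp = ev$points$wtp,
                   prob_ce = ev$points$prob_ce))
  )
  for (sheet in names(sheets))
    if (!is.null(sheets[[sheet]])) wr(sheets[[sheet]], sheet)
  invisible(dir)
}

#' Write results tables and a run manifest
#'
#' Writes the three ranking tables behind a VOI analysis — by expected
#' population incremental health benefit, by expected pNHE, and the research
#' value (EVPI) view in pNHE order — as CSV files with fixed column order,
#' plus a JSON manifest recording the settings and seed so a run can be
#' reproduced. Sort ties are broken by intervention id ascending; rerunning
#' with identical inputs and seed reproduces the files byte for byte.
#'
#' @param fit A `voi_hbp` fit (or its `results` data frame).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(fit, out_dir) {
  results <- if (inherits(fit, "voi_hbp")) fit$results else fit
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rk <- rank_interventions(results)
  cols <- c("intervention_id", "name", "provenance",
            "expected_pop_benefit", "expected_pnhe", "pnhe_lower",
            "pnhe_upper", "decision", "decision_uncertain",
            "prob_cost_effective", "evpi")
  cols <- intersect(cols, names(results))
  paths <- c(
    ranking_by_population_benefit = file.path(
      out_dir, "ranking_by_population_benefit.csv"),
    ranking_by_pnhe = file.path(out_dir, "ranking_by_pnhe.csv"),
    research_value = file.path(out_dir, "research_value.csv"))
  utils::write.csv(rk$by_population_benefit[, cols],
                   paths["ranking_by_population_benefit"], row.names = FALSE)
  utils::write.csv(rk$by_pnhe[, cols], paths["ranking_by_pnhe"],
                   row.names = FALSE)
  utils::write.csv(rk$research_value[, cols], paths["research_value"],
                   row.names = FALSE)
  if (inherits(fit, "voi_hbp")) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("voihbp")),
      seed = fit$context$seed,
      n_simulations = fit$context$n_simulations,
      time_horizon_years = fit$context$time_horizon_years,
      discount_rate = fit$context$discount_rate,
      opportunity_cost_per_daly = fit$context$opportunity_cost_per_daly,
      interval_level = fit$context$interval_level,
      settings = fit$settings,
      pooled = if (is.null(fit$pooled)) NULL else unclass(fit$pooled),
      n_include = sum(results$decision == "include"),
      n_exclude = sum(results$decision == "exclude"),
      n_uncertain = sum(results$decision_uncertain),
      n_imputed = sum(results$provenance == "imputed"))
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    paths <- c(paths, manifest = mpath)
  }
  invisible(paths)
}
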