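#' Sensitivity-analysis evidence payloads
#'
#' Published cost-effectiveness studies report uncertainty around incremental
#' costs and incremental health benefits in a handful of media. Each
#' constructor below captures one medium as a tagged payload that
#' [reconstruct_uncertainty()] later converts into a joint distribution of
#' per-patient incremental cost and benefit. The recognised media are:
#'
#' * `mean_se` — standard errors around mean incremental cost and benefit;
#' * `mean_ci` — confidence intervals around the means;
#' * `raw_pairs` — raw probabilistic-sensitivity-analysis simulations;
#' * `scatter_points` — digitized points from a cost-versus-benefit
#'   scatterplot (same payload shape as `raw_pairs`);
#' * `univariate_table` — incremental costs and benefits under single
#'   parameter changes (one row per varied parameter);
#' * `tornado_icer` — a tornado plot of ICERs under single parameter changes;
#' * `icer_histogram` — a histogram of the ICER from a probabilistic analysis;
#' * `icer_cdf` — a cumulative distribution of the ICER;
#' * `ceac` — a cost-effectiveness acceptability curve (probability
#'   cost-effective against willingness-to-pay per DALY averted).
#'
#' Digitized coordinates must be supplied as numbers; the package never reads
#' plot image files.
#'
#' @param se_cost,se_benefit Standard errors of mean incremental cost and
#'   incremental benefit (currency / DALYs per patient).
#' @param rho Optional correlation between incremental cost and benefit.
#'   When `NULL`, the pooled average correlation of the evidence base is
#'   substituted during reconstruction.
#' @param ci_cost,ci_benefit Length-2 numeric vectors `(lower, upper)`.
#' @param level Nominal coverage of the reported intervals (default 0.95).
#' @param delta_cost,delta_benefit Equal-length numeric vectors of simulated
#'   (or digitized) incremental cost / incremental benefit pairs.
#' @param rows Data frame with columns `param_id`, `dc_low`, `dc_high`,
#'   `de_low`, `de_high`: incremental cost/benefit at the low and high end of
#'   each varied parameter. `*_low`/`*_high` are the values at the parameter's
#'   low and high setting, so a cost that falls as the benefit rises keeps its
#'   sign information.
#' @param bars Data frame with columns `param_id`, `icer_low`, `icer_high`.
#' @param bin_edges Ascending numeric vector of ICER bin edges
#'   (length `length(counts) + 1`).
#' @param counts Non-negative bin counts.
#' @param points Data frame with columns `icer`, `cum_prob` (for `icer_cdf`)
#'   or `wtp`, `prob_ce` (for `ceac`).
#'
#' @return An object of class `"sa_evidence"`: a list with elements `medium`
#'   and the medium-specific payload fields.
#' @name sa_evidence
#' @examples
#' evidence_mean_se(se_cost = 30, se_benefit = 0.2, rho = 0)
#' evidence_mean_ci(ci_cost = c(40, 160), ci_benefit = c(0.6, 1.4))
NULL

new_evidence <- function(medium, payload) {
  structure(c(list(medium = medium), payload), class = "sa_evidence")
}

#' @rdname sa_evidence
#' @export
evidence_mean_se <- function(se_cost, se_benefit, rho = NULL) {
  stopifnot(is.finite(se_cost), is.finite(se_benefit))
  if (se_cost < 0 || se_benefit < 0)
    stop("standard errors must be non-negative", call. = FALSE)
  check_rho(rho)
  new_evidence("mean_se", list(se_cost = se_cost, se_benefit = se_benefit,
                               rho = rho))
}

#' @rdname sa_evidence
#' @export
evidence_mean_ci <- function(ci_cost, ci_benefit, level = 0.95, rho = NULL) {
  stopifnot(length(ci_cost) == 2L, length(ci_benefit) == 2L,
            all(is.finite(ci_cost)), all(is.finite(ci_benefit)))
  if (ci_cost[1] > ci_cost[2] || ci_benefit[1] > ci_benefit[2])
    stop("confidence interval must satisfy lower <= upper", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("interval level must lie in (0, 1)", call. = FALSE)
  check_rho(rho)
  new_evidence("mean_ci", list(ci_cost = as.numeric(ci_cost),
                               ci_benefit = as.numeric(ci_benefit),
                               level = level, rho = rho))
}

#' @rdname sa_evidence
#' @export
evidence_raw_pairs <- function(delta_cost, delta_benefit) {
  stopifnot(length(delta_cost) == length(delta_benefit),
            all(is.finite(delta_cost)), all(is.finite(delta_benefit)))
  if (length(delta_cost) < 3L)
    stop("at least 3 (cost, benefit) pairs are required", call. = FALSE)
  new_evidence("raw_pairs", list(delta_cost = as.numeric(delta_cost),
                                 delta_benefit = as.numeric(delta_benefit)))
}

#' @rdname sa_evidence
#' @export
evidence_scatter_points <- function(delta_cost, delta_benefit) {
  ev <- evidence_raw_pairs(delta_cost, delta_benefit)
  ev$medium <- "scatter_points"
  ev
}

#' @rdname sa_evidence
#' @export
evidence_univariate_table <- function(rows) {
  rows <- as.data.frame(rows)
  need <- c("param_id", "dc_low", "dc_high", "de_low", "de_high")
  if (!all(need %in% names(rows)))
    stop("univariate table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(rows) < 1L) stop("univariate table is empty", call. = FALSE)
  num <- rows[, need[-1]]
  if (!all(vapply(num, is.numeric, logical(1))) || !all(is.finite(as.matrix(num))))
    stop("univariate table ranges must be finite numbers", call. = FALSE)
  new_evidence("univariate_table", list(rows = rows))
}

#' @rdname sa_evidence
#' @export
evidence_tornado_icer <- function(bars) {
  bars <- as.data.frame(bars)
  need <- c("param_id", "icer_low", "icer_high")
  if (!all(need %in% names(bars)))
    stop("tornado payload needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(bars) < 1L) stop("tornado payload is empty", call. = FALSE)
  if (!all(is.finite(bars$icer_low)) || !all(is.finite(bars$icer_high)))
    stop("tornado ICER bounds must be finite", call. = FALSE)
  new_evidence("tornado_icer", list(bars = bars))
}

#' @rdname sa_evidence
#' @export
evidence_icer_histogram <- function(bin_edges, counts) {
  stopifnot(is.numeric(bin_edges), is.numeric(counts))
  if (length(bin_edges) != length(counts) + 1L)
    stop("need length(bin_edges) == length(counts) + 1", call. = FALSE)
  if (any(diff(bin_edges) <= 0))
    stop("bin edges must be strictly ascending", call. = FALSE)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be non-negative with positive total", call. = FALSE)
  new_evidence("icer_histogram", list(bin_edges = as.numeric(bin_edges),
                                      counts = as.numeric(counts)))
}

#' @rdname sa_evidence
#' @export
evidence_icer_cdf <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("icer", "cum_prob") %in% names(points)))
    stop("ICER CDF payload needs columns icer, cum_prob", call. = FALSE)
  if (nrow(points) < 3L)
    stop("at least 3 CDF points are required", call. = FALSE)
  points <- points[order(points$icer), , drop = FALSE]
  if (any(points$cum_prob < 0) || any(points$cum_prob > 1))
    stop("cumulative probabilities must lie in [0, 1]", call. = FALSE)
  if (any(diff(points$cum_prob) < 0))
    stop("cumulative probabilities must be non-decreasing in ICER",
         call. = FALSE)
  new_evidence("icer_cdf", list(points = points))
}

#' @rdname sa_evidence
#' @export
evidence_ceac <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("wtp", "prob_ce") %in% names(points)))
    stop("CEAC payload needs columns wtp, prob_ce", call. = FALSE)
  points <- points[order(points$wtp), , drop = FALSE]
  if (length(unique(points$wtp)) < 3L)
    stop("at least 3 distinct willingness-to-pay values are required",
         call. = FALSE)
  if (any(points$prob_ce < 0) || any(points$prob_ce > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  new_evidence("ceac", list(points = points))
}

check_rho <- function(rho) {
  if (!is.null(rho) && (!is.finite(rho) || rho < -1 || rho > 1))
    stop("correlation must lie in [-1, 1]", call. = FALSE)
  invisible(rho)
}

#' @export
print.sa_evidence <- function(x, ...) {
  cat(sprintf("Sensitivity-analysis evidence, medium '%s'\n", x$medium))
  invisible(x)
}

sa_media <- c("mean_se", "mean_ci", "raw_pairs", "scatter_points",
              "univariate_table", "tornado_icer", "icer_histogram",
              "icer_cdf", "ceac")

#' Per-intervention record of an evidence base
#'
#' Holds the 'best guess' point estimates of per-patient incremental cost and
#' incremental health benefit, the population that stands to benefit, and the
#' sensitivity-analysis evidence (if any) reported by the source study.
#'
#' @param id Unique identifier within the evidence base.
#' @param name Display name; defaults to `id`.
#' @param delta_cost_pp Incremental cost per patient (currency).
#' @param delta_benefit_pp Incremental health benefit per patient (DALYs
#'   averted; may be negative).
#' @param eligible_population Annual cohort of persons eligible to receive the
#'   intervention.
#' @param coverage Achievable coverage of the eligible population, in
#'   `[0, 1]`.
#' @param evidence An [sa_evidence] payload, or `NULL` when the source study
#'   reported no sensitivity analysis (triggers pooled-average imputation).
#'
#' @return An object of class `"intervention"`.
#' @examples
#' intervention("itn", "Insecticide-treated nets", delta_cost_pp = 50,
#'              delta_benefit_pp = 1.2, eligible_population = 1e5,
#'              coverage = 0.6,
#'              evidence = evidence_mean_se(20, 0.4, rho = 0.2))
#' @export
intervention <- function(id, name = id, delta_cost_pp, delta_benefit_pp,
                         eligible_population, coverage, evidence = NULL) {
  id <- as.character(id)
  if (!nzchar(id)) stop("intervention id must be non-empty", call. = FALSE)
  stopifnot(is.finite(delta_cost_pp), is.finite(delta_benefit_pp),
            is.finite(eligible_population), is.finite(coverage))
  if (eligible_population < 0)
    stop("eligible_population must be >= 0", call. = FALSE)
  if (coverage < 0 || coverage > 1)
    stop("coverage must lie in [0, 1]", call. = FALSE)
  if (!is.null(evidence) && !inherits(evidence, "sa_evidence"))
    stop("evidence must be an sa_evidence payload or NULL", call. = FALSE)
  structure(
    list(id = id, name = as.character(name),
         delta_cost_pp = delta_cost_pp, delta_benefit_pp = delta_benefit_pp,
         eligible_population = eligible_population, coverage = coverage,
         evidence = evidence),
    class = "intervention"
  )
}

#' @export
print.intervention <- function(x, ...) {
  cat(sprintf("Intervention '%s' (%s)\n", x$id, x$name))
  cat(sprintf("  per patient: cost %.4g, benefit %.4g DALYs\n",
              x$delta_cost_pp, x$delta_benefit_pp))
  cat(sprintf("  population:  %.4g eligible/year at coverage %.2f\n",
              x$eligible_population, x$coverage))
  cat(sprintf("  evidence:    %s\n",
              if (is.null(x$evidence)) "none (imputation candidate)"
              else x$evidence$medium))
  invisible(x)
}

#' Assemble an evidence base
#'
#' @param context A [decision_context()].
#' @param interventions A list of [intervention()] records with unique ids.
#' @return An object of class `"evidence_base"`.
#' @examples
#' eb <- evidence_base(decision_context(), list(
#'   intervention("a", delta_cost_pp = 61, delta_benefit_pp = 2,
#'                eligible_population = 1000, coverage = 1,
#'                evidence = evidence_mean_se(10, 0.1, rho = 0))))
#' @export
evidence_base <- function(context, interventions) {
  if (!inherits(context, "decision_context"))
    stop("context must be a decision_context", call. = FALSE)
  if (length(interventions) < 1L)
    stop("evidence base needs at least one intervention", call. = FALSE)
  ok <- vapply(interventions, inherits, logical(1), what = "intervention")
  if (!all(ok))
    stop("all elements must be intervention records", call. = FALSE)
  ids <- vapply(interventions, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate intervention id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(interventions) <- ids
  structure(list(context = context, interventions = interventions),
            class = "evidence_base")
}

#' @export
print.evidence_base <- function(x, ...) {
  n <- length(x$interventions)
  media <- vapply(x$interventions, function(iv)
    if (is.null(iv$evidence)) "none" else iv$evidence$medium, character(1))
  cat(sprintf("Evidence base: %d intervention%s\n", n, if (n == 1) "" else "s"))
  tab <- table(media)
  cat("  evidence media: ",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  print(x$context)
  invisible(x)
}

#' Validate an evidence base
#'
#' Runs the full set of invariant checks and returns a data frame of
#' diagnostics rather than raising errors, so a workbook can be checked in one
#' pass. An empty data frame means the base is valid.
#'
#' @param eb An [evidence_base()].
#' @return Data frame with columns `intervention_id`, `field`, `message`
#'   (zero rows when valid).
#' @export
validate_evidence_base <- function(eb) {
  diags <- list()
  note <- function(id, field, message) {
    diags[[length(diags) + 1L]] <<- data.frame(
      intervention_id = id, field = field, message = message,
      stringsAsFactors = FALSE)
  }
  if (!inherits(eb, "evidence_base")) {
    note(NA_character_, "class", "not an evidence_base object")
    return(do.call(rbind, diags))
  }
  ids <- vapply(eb$interventions, `[[`, character(1), "id")
  for (dup in unique(ids[duplicated(ids)]))
    note(dup, "id", "duplicate intervention id")
  for (iv in eb$interventions) {
    if (iv$eligible_population < 0)
      note(iv$id, "eligible_population", "must be >= 0")
    if (iv$coverage < 0 || iv$coverage > 1)
      note(iv$id, "coverage", "must lie in [0, 1]")
    if (!is.finite(iv$delta_cost_pp))
      note(iv$id, "delta_cost_pp", "must be finite")
    if (!is.finite(iv$delta_benefit_pp))
      note(iv$id, "delta_benefit_pp", "must be finite")
    ev <- iv$evidence
    if (!is.null(ev)) {
      if (!ev$medium %in% sa_media)
        note(iv$id, "medium", paste("unknown evidence medium", ev$medium))
      if (ev$medium == "icer_cdf" && any(diff(ev$points$cum_prob) < 0))
        note(iv$id, "cum_prob", "ICER CDF must be non-decreasing")
      if (ev$medium %in% c("icer_cdf", "ceac")) {
        p <- if (ev$medium == "icer_cdf") ev$points$cum_prob else ev$points$prob_ce
        if (any(p < 0 | p > 1))
          note(iv$id, "probability", "probabilities must lie in [0, 1]")
      }
      if (ev$medium == "mean_se" && (ev$se_cost < 0 || ev$se_benefit < 0))
        note(iv$id, "se", "standard errors must be non-negative")
    }
  }
  if (length(diags) == 0L)
    return(data.frame(intervention_id = character(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, diags)
}
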