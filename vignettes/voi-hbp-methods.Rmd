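---
title: "Methods: reconstructing joint uncertainty and valuing research for health benefits packages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing joint uncertainty and valuing research for health benefits packages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voihbp)
```

## The decision problem

A health benefits package (HBP) is the set of interventions a health system
funds from its pooled budget. Each candidate intervention $i$ is summarised
by a per-patient incremental cost $\Delta c_i$ (against the status quo) and a
per-patient incremental health benefit $\Delta e_i$ in DALYs averted.
Spending displaces health elsewhere in the system at the health opportunity
cost $k$ (currency per DALY averted), so the per-patient *net health effect*
is

$$\mathrm{nhe}_i = \Delta e_i - \Delta c_i / k .$$

Scaling by the annual eligible population $N_i$, achievable coverage $c_i$,
and the discounted delivery horizon gives the *population net health effect*

$$\mathrm{pNHE}_i = \mathrm{nhe}_i \cdot N_i \, c_i \, A, \qquad
A = \sum_{t=0}^{T-1} (1+r)^{-t},$$

with horizon $T$ years and discount rate $r$ (first year undiscounted). An
intervention belongs in the package when its expected pNHE is positive. The
defaults — $T = 20$, $r = 0.03$, $k = 61$ US\$/DALY — correspond to a
low-income-country HBP exercise; all three are ordinary arguments of
`decision_context()`.

Because $\Delta c_i$ and $\Delta e_i$ are uncertain, the pNHE has a
probability distribution. Two distinct questions follow:

* **Adoption**: is expected pNHE positive?
* **Research**: if the plausible pNHE range spans both net losses and net
  gains, how much health could research that resolved the uncertainty be
  expected to save? This is the per-decision expected value of perfect
  information (EVPI):
  $$\mathrm{EVPI} = E[\max(\mathrm{pNHE}, 0)] - \max(E[\mathrm{pNHE}], 0).$$

EVPI is reported on the same discounted, population net-DALY scale as pNHE;
no research-delay or research-cost adjustment is applied, so it is the
*maximum* value research could have.

## Reconstructing joint uncertainty from published summaries

Published cost-effectiveness studies rarely provide the joint distribution
of $(\Delta c, \Delta e)$. They report one of a handful of summaries, and
the package inverts each back to a standard deviation pair
$(\sigma_C, \sigma_E)$ and correlation $\rho$, assuming a bivariate normal
on the incremental scale (the weakest family expressible from variances and
a correlation alone; raw simulations can instead be retained as an empirical
sample and resampled). The inversions:

| medium | inversion |
|---|---|
| standard errors | identity: $\sigma = \mathrm{SE}$ |
| confidence intervals | $\sigma = (\text{upper} - \text{lower}) / (2 z_{(1+\ell)/2})$ per margin |
| raw simulations / scatter | sample moments ($n-1$ denominator) or empirical resampling |
| univariate table | per-parameter variances $w^2/12$ and signed covariances $w_C w_E / 12$, summed over independent parameters |
| tornado of ICERs | total ICER variance from bar widths; attributed to one margin |
| ICER histogram | conditional multinomial ML fit of $(\sigma_C, \sigma_E)$ to bin counts under the ratio distribution |
| ICER CDF | least-squares fit of the ratio CDF to the reported points |
| CEAC | constrained least squares of $\Phi(m(\lambda)/s(\lambda))$ for $(\sigma_C, \sigma_E, \rho)$ |

Choices that were genuinely open, and why they were made this way:

* **Univariate ranges** default to the *extremes-of-a-uniform* reading
  (variance $= \text{width}^2/12$): one-at-a-time scenario endpoints are
  usually plausible extremes, not confidence limits. An `interval95`
  convention (half-range read as a 95% normal half-interval) is available
  where a study states its ranges are interval-based. Parameter
  contributions are summed as independent — a one-at-a-time analysis carries
  no joint information, so independence is the only defensible default.
  A single varied parameter forces $|\rho| = 1$; the sign follows the
  co-movement of cost and benefit across the range.
* **Tornado plots of ICERs** carry no information splitting uncertainty
  between the two margins. By default the whole ICER spread is attributed to
  cost ($\sigma_C = \mathrm{sd(ICER)}\cdot|\Delta \bar e|$, benefit held at
  its point estimate), which leaves the DALY estimate untouched when the
  medium says nothing about it. The `benefit` attribution maps the 95% ICER
  interval through $\Delta e = \Delta \bar c / \mathrm{ICER}$ and reads the
  half-width of the image interval as a 95% normal half-interval; it refuses
  ICER intervals spanning zero, where the map is undefined.
* **ICER histograms and CDFs** observe only the one-dimensional ratio
  $\Delta C / \Delta E$, which cannot identify three shape parameters, so
  $\rho$ is held fixed (at the pooled average of the informed interventions,
  or a supplied value) and only $(\sigma_C, \sigma_E)$ are fitted. The ratio
  CDF is evaluated by splitting on the sign of the denominator,
  $P(C/E \le t) = P(C - tE \le 0, E > 0) + P(C - tE \ge 0, E < 0)$, each a
  bivariate-normal rectangle probability — exact, with no moment conditions
  (the ratio of normals has none). For *histograms* the bin probabilities
  are conditioned on the displayed support and fitted by multinomial maximum
  likelihood: published histograms clip tail mass, and after support
  renormalisation a least-squares CDF distance develops a near-flat valley
  (inflating $\sigma_C$ while the renormalisation compensates), whereas the
  likelihood keeps the thinly populated tail bins informative. Parameter
  recovery on simulated 20-bin histograms of $10^5$ draws is within a few
  percent. For *CDF points*, which are not renormalised, plain least squares
  is used. Both fits multi-start the bounded optimizer (L-BFGS-B, 200
  iterations) from five deterministic points; ties break to the smaller
  residual, then the smaller $\sigma_C$. A residual above 0.01 attaches a
  poor-fit diagnostic instead of failing — a non-normal or non-unimodal
  payload still returns its best projection, loudly.
* **CEAC inversion** uses the closed form
  $P(\lambda \Delta E - \Delta C \ge 0) = \Phi(m(\lambda)/s(\lambda))$ with
  $m(\lambda) = \lambda \Delta\bar e - \Delta\bar c$ and
  $s(\lambda)^2 = \lambda^2\sigma_E^2 - 2\lambda\rho\sigma_E\sigma_C +
  \sigma_C^2$. Since $s^2$ is quadratic in $\lambda$, inverting the
  probabilities to the z-scale yields a linear system whose solution seeds
  the constrained optimizer; with exactly three distinct willingness-to-pay
  points the fit must interpolate (residual $< 10^{-4}$) or reconstruction
  fails with the residual attached — three points that cannot be
  interpolated are inconsistent with the stated means, and smoothing over
  that silently would manufacture information. Saturated curves
  (probabilities all 0 or all 1) are rejected as unidentifiable.
* **Degenerate margins** ($\sigma = 0$) force $\rho = 0$ with a diagnostic
  rather than an error: a point-mass margin is a legitimate limit (e.g. a
  zero-width interval), and any correlation against it is vacuous.

Correlations absent from a medium (standard errors or intervals reported
without one) are filled with the pooled average correlation of the
interventions whose media do pin one; reconstruction therefore runs in two
passes inside `voi_hbp()`.

## Simulation and seeding

Each intervention's pNHE distribution is produced by Monte Carlo:
$(\Delta c, \Delta e)$ pairs are drawn from the reconstructed joint
distribution (Cholesky combination of two standard-normal streams, or
recentred resampling for the empirical family), mapped to per-patient net
health effects, and scaled by $N c A$. One pair is drawn per simulation and
applied to all years — the uncertainty being propagated is about the *true*
values, not year-to-year fluctuation, which is what a value-of-information
question concerns. Negative sampled costs or benefits are legitimate
incremental quantities and are never truncated.

$N$ is interpreted as an annual eligible cohort treated in each of the $T$
years, so annual effects are summed with the discount annuity $A$; a
`prevalent_pool` option replaces $A$ by 1 for one-off populations. Costs are
converted to the DALY scale by a single division by $k$ *before* draws are
assembled, which makes the distribution exactly invariant — bit for bit
under matched seeds — to rescaling all cost quantities and $k$ by a common
factor (a currency redenomination must not change health conclusions).

Per-intervention seeds are derived by a stable polynomial hash of the
intervention id added to the master seed, so each intervention owns a
reproducible stream regardless of workbook order, and adding or removing
interventions leaves the others' draws untouched.

The default draw count is $10^5$, at which the Monte Carlo standard error of
an EVPI estimate is well under 1% of the pNHE interval width for the regimes
of interest; summaries use equal-tail type-7 empirical quantiles.

## Decision classification and EVPI

`include` requires strictly positive expected pNHE (a zero-mean intervention
offers nothing over the displaced alternatives). Decision uncertainty is
flagged when the equal-tail interval at `interval_level` (default 95%; the
level is a reporting convention, not an inferential threshold) spans zero.
EVPI is computed from the draws as
$\mathrm{mean}(\max(d,0)) - \max(\mathrm{mean}(d), 0)$, clamped at zero
against floating rounding. Because pNHE is a linear map of a bivariate
normal, it is itself normal, and the closed form
$\sigma\varphi(\mu/\sigma) - |\mu|\Phi(-|\mu|/\sigma)$ serves as an
independent oracle for the Monte Carlo estimator in the test suite — the
two agree within three Monte Carlo standard errors across $\mu/\sigma \in
[-5, 5]$.

Three rankings are produced: by expected population incremental health
benefit (gross of costs), by expected pNHE, and a research-value view that
keeps the pNHE ordering with EVPI attached so the value of research can be
read directly against the adoption ranking. All ties break by intervention
id for reproducibility.

## Pooling and exploratory imputation

Interventions whose source studies reported no sensitivity analysis receive
the *average of the values extracted* from the informed set: pooled
$\bar\sigma_C$, $\bar\sigma_E$, $\bar\rho$ copied directly
(`absolute` mode, the default, matching the wording of the approach this
implements) or pooled coefficients of variation rescaled by the
intervention's own point estimates (`relative` mode). Both are provided
because averaging absolute variances across interventions whose cost scales
differ by orders of magnitude is statistically questionable, while the
relative mode degenerates when a point estimate is zero; the chosen mode is
recorded in the run manifest. Degenerate entries contribute to the
standard-deviation averages but not the CV averages. Imputed results carry
`provenance = "imputed"` in every output row — they are exploratory, and
should be read as "if this intervention's uncertainty resembles the informed
average", not as evidence.

## What the synthetic generator does and does not emulate

`generate_evidence_base()` renders payloads in all nine media from known
bivariate-normal truths: summary media exactly, sampled media ($10^4$ pairs,
$10^5$ histogram draws over 20 bins between the 0.5% and 99.5% quantiles)
under derived seeds, CDFs and CEACs from the exact closed forms. The
21-intervention demonstration table spans the media mix observed in a real
HBP evidence review (5 univariate tables, 2 tornado plots, 2 raw simulation
sets, 1 scatterplot, 1 ICER histogram, 1 ICER CDF, 8 confidence intervals,
1 standard error) and places per-patient net-benefit z-scores
$\mu/\sigma$ either beyond $\pm 3$ (clearly cost-effective / clearly not) or
inside $\pm 1.96$ (decision-uncertain), with none in between, so
classification checks are unambiguous. Tornado truths carry
$\sigma_E = 0$ (that medium cannot transport benefit-margin spread),
histogram/CDF truths use $\rho = 0$, and the remaining correlations are
balanced to average zero so the pooled default those fits rely on matches
the truths. One intervention pairs a large gross health benefit with a
clearly negative net effect, reproducing the situation where the benefit and
net-health rankings disagree.

The generator emulates *reporting*, not *epidemiology*: truths are exactly
bivariate normal, payloads are internally consistent with the point
estimates, and populations are static. Passing recovery tests therefore
demonstrates that the inversions are correct inverses of the media under the
stated assumptions — not that real published summaries (asymmetric
intervals, skewed cost distributions, inconsistent digitization) obey those
assumptions. Asymmetry and fit residual diagnostics are the instrument for
spotting such violations in real data.

## Known limitations

* A single parametric family (bivariate normal) on the incremental scale;
  no lognormal-cost option, no Bayesian reconstruction.
* Per-decision EVPI only: no per-parameter EVPPI (the media carry no
  parameter-level structure) and no EVSI for concrete study designs.
* No correlation of uncertainty across interventions, no transmission
  dynamics, no coverage ramp-up, no equity weighting — rankings are one
  input to deliberation, not a prescription.
* Confidence intervals are inverted symmetrically; asymmetric intervals are
  squeezed into a symmetric $\sigma$, which understates skewness.

## A worked example

```{r example}
eb <- evidence_base(
  decision_context(n_simulations = 20000, seed = 7),
  list(
    intervention("circ", "circumcision-like, uncertain best buy",
                 delta_cost_pp = 60, delta_benefit_pp = 1.1,
                 eligible_population = 5e4, coverage = 0.5,
                 evidence = evidence_mean_se(40, 0.8, rho = 0.1)),
    intervention("tb", "clear best buy",
                 delta_cost_pp = 30, delta_benefit_pp = 2,
                 eligible_population = 1e5, coverage = 0.8,
                 evidence = evidence_mean_ci(c(10, 50), c(1.6, 2.4))),
    intervention("gap", "no sensitivity analysis published",
                 delta_cost_pp = 75, delta_benefit_pp = 1.2,
                 eligible_population = 3e4, coverage = 0.6)))
fit <- voi_hbp(eb)
summary(fit)
```

The uncertain intervention attracts essentially all the research value; the
clear best buy attracts none, however wide its benefit uncertainty; and the
imputed row is flagged as exploratory.
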