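# voihbp

Value-of-information analysis for health benefits package (HBP) design.

Governments assembling an HBP — the set of interventions funded from pooled
health budgets — must decide, per intervention, whether the health it
generates exceeds the health its costs displace elsewhere in the system, and
whether the evidence behind that decision is solid enough or worth improving
through research. `voihbp` answers both questions using only what published
cost-effectiveness studies actually report.

## The model

For intervention $i$ with per-patient incremental cost $\Delta c_i$ and
incremental benefit $\Delta e_i$ (DALYs averted), the population net health
effect over a $T$-year horizon at discount rate $r$ and health opportunity
cost $k$ (currency per DALY averted) is

$$\mathrm{pNHE}_i = \left(\Delta e_i - \frac{\Delta c_i}{k}\right)
  N_i\, c_i \sum_{t=0}^{T-1}(1+r)^{-t},$$

with $N_i$ the annual eligible population and $c_i$ achievable coverage.
Include when $E[\mathrm{pNHE}_i] > 0$. The value of research is the
per-decision expected value of perfect information,

$$\mathrm{EVPI}_i = E[\max(\mathrm{pNHE}_i, 0)] - \max(E[\mathrm{pNHE}_i], 0),$$

in net DALYs averted: the expected health forgone by deciding under current
uncertainty.

The distribution of $(\Delta c_i, \Delta e_i)$ is rarely published, so the
package reconstructs it — standard deviations $\sigma_C, \sigma_E$ and
correlation $\rho$ under a bivariate normal, or an empirical sample — from
whichever sensitivity-analysis medium the source study reported: standard
errors, confidence intervals, raw probabilistic simulations, scatterplots,
one-at-a-time univariate tables, tornado plots of ICERs, ICER histograms,
ICER cumulative distributions, or cost-effectiveness acceptability curves.
Interventions with no sensitivity analysis at all are handled by an
exploratory analysis that borrows the average reconstructed uncertainty of
the informed interventions, flagged as imputed in every output. The methods
vignette (`vignettes/voi-hbp-methods.Rmd`) derives each inversion and states
its assumptions.

## A worked example

```r
library(voihbp)
eb <- evidence_base(
  decision_context(n_simulations = 20000, seed = 7),   # T=20y, r=3%, k=$61
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
#> VOI analysis of 3 intervention(s)
#>   horizon 20 years (annuity 15.3238), k = 61 per DALY, n = 20000 draws
#>   include: 2, exclude: 1, decisions uncertain: 2, imputed: 1
#>   top research priorities (by EVPI, net DALYs averted):
#>  intervention_id expected_pnhe decision decision_uncertain      evpi
#>             circ     46646.256  include               TRUE 127526.16
#>              gap     -7394.995  exclude               TRUE  63667.95
#>               tb   1852148.223  include              FALSE      0.00
```

Reading it: `tb` is expected to avert 1.85 million net DALYs and its 95%
interval lies entirely above zero — include it, and research on it is
worthless however uncertain its effect size, because no plausible outcome
changes the decision. `circ` is expected to be (just) cost-effective but its
interval spans −686 thousand to +776 thousand net DALYs, so the inclusion
could be wrong; perfect information would be worth 127 526 net DALYs — the
top research priority. `gap`, with no published sensitivity analysis, gets
the informed set's average uncertainty (provenance `imputed`) and its
exploratory EVPI should be read as a prompt for expert review, not evidence.

`write_results(fit, "results/")` emits the three ranking tables (by gross
population health benefit, by pNHE, and research value) plus a JSON run
manifest. `plot(fit)` draws the pNHE ranking with error bars. A synthetic
21-intervention evidence base with known ground truth is available via
`generate_evidence_base()`, and a command-line front end
(`inst/cli/voihbp.R`) exposes `run`, `fixture` and `validate` subcommands.

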