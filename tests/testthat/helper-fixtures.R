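# Shared helpers: tiny evidence bases built in code.

make_iv <- function(id = "a", dc = 61, de = 2, N = 1000, cov = 1,
                    evidence = evidence_mean_se(10, 0.1, rho = 0)) {
  intervention(id, paste("intervention", id), delta_cost_pp = dc,
               delta_benefit_pp = de, eligible_population = N,
               coverage = cov, evidence = evidence)
}

make_eb <- function(interventions = list(make_iv()),
                    ctx = decision_context(n_simulations = 2000, seed = 42)) {
  evidence_base(ctx, interventions)
}

# bivariate normal draws for forward-recovery oracles
rbvn <- function(n, mc, me, sc, se, rho, seed) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  data.frame(delta_cost = mc + sc * z1,
             delta_benefit = me + se * (rho * z1 + sqrt(1 - rho^2) * z2))
}
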