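Package: voihbp
Title: Value of Information Analysis for Health Benefits Package Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the value of further research for healthcare
    interventions considered for inclusion in a health benefits package.
    Reconstructs joint uncertainty in per-patient incremental costs and
    incremental health benefits (DALYs averted) from the heterogeneous
    sensitivity-analysis summaries reported in published cost-effectiveness
    studies (standard errors, confidence intervals, raw probabilistic
    simulations, scatterplots, univariate tables, tornado plots of ICERs,
    ICER histograms and cumulative distributions, cost-effectiveness
    acceptability curves), simulates population net health effects (pNHE)
    in net DALYs averted over a discounted delivery horizon, classifies
    inclusion decisions and decision uncertainty, and computes the expected
    value of perfect information (EVPI) per intervention to rank research
    priorities. Includes a synthetic evidence-base generator with known
    ground truth and pooled-average imputation for interventions lacking
    sensitivity-analysis data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mvtnorm,
    stats,
    graphics,
    tools,
    utils
Suggests:
    readxl,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
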