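Package: umediate
Title: Sensitivity of Mediation Analysis to Unmeasured Confounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based sensitivity analysis for unmeasured confounding in
    causal mediation analysis. Generates exposure-mediator-outcome systems with
    measured and unmeasured confounders from user-specified structural equations
    (identity or logit links), estimates natural direct and mediated effects with
    a quasi-Bayesian Monte-Carlo counterfactual estimator both including and
    excluding the unmeasured confounders, and summarises how significance,
    sign and magnitude of the mediated (ACME) and direct (ADE) effects change.
    Supports mediator-exposure interactions on the outcome, effect-size sweeps,
    and seed-substream partitioning so large studies can be split across
    machines and merged exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
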