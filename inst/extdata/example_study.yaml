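# Example umediate study configuration.
# One hypothetical unmeasured confounder (e.g. an unmeasured ancestry
# principal component) confounding the exposure-mediator-outcome system.
n: 1000
n_sim: 100
seed: 1
measured_confounders:
  - kind: normal
    mean: 0
    variance: 1
    label: age
unmeasured_confounders:
  - kind: normal
    mean: 0
    variance: 1
exposure:
  family: normal
  gamma0: 0
  gamma_c: [0.2]
  gamma_u: [1.0]
  sigma: 1
mediator:
  family: normal
  alpha0: 0
  alpha_a: 0.5
  alpha_c: [0.2]
  alpha_u: [1.0]
  sigma: 1
outcome:
  family: normal
  beta0: 0
  beta_a: 0.3
  beta_m: 0.8
  beta_i: 0
  beta_c: [0.2]
  beta_u: [1.0]
  sigma: 1
options:
  n_draws: 1000
  alpha: 0.05
  treat: 1
  control: 0
  interaction: false
sweep_grid: [0, 1, 2, 4]
output_prefix: results/example
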