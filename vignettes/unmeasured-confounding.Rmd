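---
title: "Assessing unmeasured confounding in mediation analysis by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing unmeasured confounding in mediation analysis by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umediate)
```

## The problem

Mediation analysis decomposes the total effect of an exposure $A$ on an
outcome $Y$ into the part transmitted through a mediator $M$ — the average
causal mediation effect (ACME) — and the remaining direct part (ADE).
Identification of these counterfactual quantities requires that no
unmeasured variable confounds the $A$–$M$, $A$–$Y$ or $M$–$Y$
relationships. In observational settings this assumption is rarely
credible: in population-based genetic studies, for example, residual
population stratification not captured by the measured ancestry principal
components can confound all three relationships simultaneously, because a
subject's genotype is not randomized with respect to ancestry.

umediate takes a simulation-based (not a theoretical) approach to the
question *"how much would my conclusions change if such a confounder
existed?"*. The user writes down a fully parameterised generative system
including one or more hypothetical unmeasured confounders $U$; the package
repeatedly simulates from it, analyses each dataset twice — adjusting and
not adjusting for $U$ — and reports how often the two analyses agree.

## The generative model

A scenario consists of measured confounders $C$, unmeasured confounders
$U$ (each independently normal with user-chosen mean and variance, or
Bernoulli with user-chosen probability), and three structural equations:

$$E[A] = \gamma_0 + \gamma_C C + \gamma_U U$$
$$E[M] = \alpha_0 + \alpha_A A + \alpha_C C + \alpha_U U$$
$$E[Y] = \beta_0 + \beta_A A + \beta_M M + \beta_I A M + \beta_C C + \beta_U U$$

Each of $A$, $M$, $Y$ is either normal (identity link: the variable is its
linear predictor plus Gaussian noise) or Bernoulli (the identity link is
replaced by the logit link and the variable is a 0/1 draw at the expit of
the linear predictor). Variables are generated in the order $C, U
\rightarrow A \rightarrow M \rightarrow Y$. The $\beta_I$ term allows an
exposure–mediator interaction on the outcome.

Assumptions worth keeping in mind:

* all confounders are mutually independent — in particular there is **no
  correlation between $C$ and $U$**. This is reasonable when both are
  orthogonal ancestry components, and must be judged by the user otherwise;
* a single mediator;
* no interactions of $C$ or $U$ with $A$ or $M$ on the outcome;
* the regressions rely on standard GLM asymptotics, so sample sizes should
  comfortably exceed 30 (`simulate_dataset()` warns below that).

The structural equations specify only the means; for normal-family
variables a residual standard deviation is also needed. These are
user-settable (`sigma` in each model constructor) and default to 1, the
standard convention in structural-equation simulation.

## The estimator

`estimate_mediation()` implements the quasi-Bayesian Monte-Carlo
counterfactual algorithm. With exposure contrast $a^* \rightarrow a$
(default $0 \rightarrow 1$):

1. fit the mediator regression $M \sim 1 + A + C\,(+\,U)$ and the outcome
   regression $Y \sim 1 + A + M\,(+\,A{:}M)\,(+\,C, U)$, each with its
   declared family (least squares or logistic ML);
2. draw `n_draws` coefficient vectors for each fit from multivariate
   normals centred at the estimates with the estimated covariances, the two
   models independent of one another;
3. per draw, simulate potential mediators $M_i(a)$ for every observation
   and both exposure levels — normal mediators receive residual noise at
   the fitted residual SD (this matters when the outcome is nonlinear in
   $M$, i.e. for logit outcomes or interactions), Bernoulli mediators are
   0/1 draws at the expit of their linear predictor. The two exposure
   levels share each individual's residual draw (for Bernoulli mediators,
   the same uniform variate): this is the rank-preserving counterfactual
   reading of "the same individual under both exposures", leaves every
   expected effect unchanged by linearity of expectation, and keeps the
   within-individual contrast $M_i(a) - M_i(a^*)$ free of independent
   noise whose mean would otherwise inflate the ACME draw spread beyond
   the estimator's actual sampling uncertainty and render the
   interval-based test badly conservative under the null;
4. evaluate expected potential outcomes $Y_i(a, m)$ from the outcome
   model's mean function only — outcome residual noise would average out of
   the effects, so none is added;
5. form the mediated contrast
   $\delta(a) = \overline{Y_i(a, M_i(a)) - Y_i(a, M_i(a^*))}$ and direct
   contrast $\zeta(a) = \overline{Y_i(a, M_i(a)) - Y_i(a^*, M_i(a))}$, and
   average each over the two reference levels: the draw's ACME is
   $(\delta(a) + \delta(a^*))/2$, its ADE $(\zeta(a) + \zeta(a^*))/2$, and
   its total effect their sum (so additivity holds exactly per draw);
6. the point estimate is the **mean** over draws (not the median — a
   deliberate choice matching the symmetric percentile-interval reporting;
   users comparing against median-summarising implementations should expect
   sub-Monte-Carlo-error differences); the interval is the
   $\alpha/2, 1-\alpha/2$ percentile interval of the draws; an effect is
   *significant* when its interval excludes 0.

Covariates enter at their observed per-observation values, i.e. effects are
empirically averaged over the covariate distribution. Non-convergence of
either regression (including logistic separation) flags the result rather
than raising an error; the study loop records and excludes such iterations
while reporting their count, so they can never bias a summary silently.

For all-normal scenarios the effects have closed forms
(`closed_form_effects()`):
$$\mathrm{ACME} = \alpha_A (a - a^*)\left(\beta_M + \beta_I \tfrac{a + a^*}{2}\right),
\qquad
\mathrm{ADE} = (a - a^*)\left(\beta_A + \beta_I \tfrac{\mu_M(a) + \mu_M(a^*)}{2}\right)$$
with $\mu_M(a)$ the marginal mediator mean. This is the package's internal
oracle: the test suite verifies the Monte-Carlo estimator against it over a
grid of coefficient settings, and verifies the *without-U* estimates
against large-sample population-projection fits (the omitted-variable-bias
limits). No closed form exists for logit links; there the Monte-Carlo
estimator is the only route.

## The sensitivity loop

`run_umediation()` repeats, for each iteration: simulate one dataset;
estimate with `include_u = FALSE` and with `include_u = TRUE` **on the same
data**; record both results and the dataset's correlation matrix. The
summary reports, over converged iterations:

* the proportion of iterations with a significant ACME / ADE in each arm;
* the proportion of iterations whose *conclusions match*: both arms
  non-significant, or both significant **with the same sign**. (Matching on
  significance status alone would count sign-reversed significant effects
  as agreement, which misrepresents what an analyst would conclude; the
  sign condition is therefore part of the definition here.)
* average estimates per arm and the average absolute with/without-U
  difference;
* the elementwise mean of the per-iteration correlation matrices — a
  stable, interpretable summary of how the chosen coefficients translate
  into observable associations. (Per-dataset matrices are kept in the
  records if a single-realisation view is wanted.)

### Seeds, partitioning and merging

Every iteration derives its own substreams from
`(master_seed, iteration)` via a congruential hash
(`substream_seed()`) — one stream for data generation and one per
estimation arm. Results therefore depend only on the iteration's key, not
on which process runs it: a 10 000-iteration study can be split across
machines with disjoint `iterations =` subsets, the per-iteration CSVs
merged with `merge_records()` (which rejects duplicate keys), and the
merged summary is **bit-identical** to the monolithic run. The records CSV
stores doubles at 17 significant digits so the file round trip preserves
this exactness.

### Effect-size sweeps

`sweep_confounder_effect()` varies the confounding strength by setting
$\gamma_U = \alpha_U = \beta_U = e$ for every $U$ simultaneously over a
grid of $e$ — the natural single-parameter axis for "how strong would
confounding have to be before my conclusions change". Each grid point runs
a full study on a seed derived from `(master_seed, grid index)`.
`plot_sweep()` draws the match-proportion curves, one panel per sweep
(e.g. one vs. two unmeasured confounders).

## Numerical and design notes

* **Exposure contrast.** Continuous exposures default to the unit contrast
  $0 \rightarrow 1$; set `treat` / `control` for other scales.
* **Significance.** Interval-based (percentile interval excludes 0), not
  p-value based — the natural criterion for a Monte-Carlo draw
  distribution.
* **Degenerate inputs.** Zero-variance columns make the correlation matrix
  entries `NA` (undefined, never silently 0); rank-deficient designs raise
  an error naming the collinear terms; `n <= 30` warns.
* **Reordering covariates.** Relabelling or reordering $C$ columns leaves
  the fitted regressions invariant; the coefficient *draws*, however, come
  from an eigendecomposition whose sign conventions are not stable under
  permutation, so fixed-seed results agree at the draw-mean noise level
  ($\mathrm{sd(draws)}/\sqrt{\texttt{n\_draws}}$) rather than bitwise.
* **Checked problem sizes.** The validation suite exercises: oracle
  recovery over 20 coefficient settings at $n = 5000$ with 1000 draws;
  null calibration of the ACME test over 500 replicates at $n = 500$;
  omitted-variable-bias limits from a single $n = 10^6$ projection fit
  against 100-iteration averages at $n = 5000$; partition invariance over
  50 iterations; the no-confounding fixed point at $n = 1000$ over 200
  iterations; and simulator moment laws at $n = 10^6$ (covariances checked
  at 1% on the standardized scale, which equals relative 1% for the
  non-zero entries and gives the structurally-zero $C$–$U$ entry a
  meaningful absolute bound).

## What the simulations do and do not show

The generator emulates exactly the world the structural equations describe:
linear/logistic links, independent confounders, homoscedastic Gaussian
noise, a single mediator. Passing checks demonstrate that the estimator and
the sensitivity loop are correct *under that model*. Real data can deviate
in ways the framework deliberately does not model — correlated measured and
unmeasured confounders, nonlinear dose–response, measurement error in $M$,
multiple or sequential mediators, confounder-by-exposure interactions — and
conclusions about robustness to $U$ are conditional on the user's
hypothesised path coefficients being in a plausible range. The intended use
is bracketing: run sweeps over the defensible range of confounder effects
(e.g. bounded by the strongest *measured* confounder, as when unmeasured
ancestry components are benchmarked against measured principal components)
and report how conclusions move across it.

## A worked miniature

```{r example, eval = FALSE}
scenario <- mediation_scenario(
  unmeasured = list(normal_confounder(0, 1)),
  exposure   = exposure_model(gamma_u = 1),
  mediator   = mediator_model(alpha_a = 0.5, alpha_u = 1),
  outcome    = outcome_model(beta_a = 0.3, beta_m = 0.8, beta_u = 1))

study <- run_umediation(scenario, n = 1000, n_sim = 100, master_seed = 1)
study$summary

sweep <- sweep_confounder_effect(scenario, grid = c(0, 1, 2, 4),
                                 n = 1000, n_sim = 100, master_seed = 1)
plot_sweep(sweep, "sweep.png")
```

The same study is reproducible from the command line via the bundled
script (`system.file("cli", "umediate.R", package = "umediate")`) with a
YAML configuration; see the README for the dialect.
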