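#' Options for the counterfactual mediation estimator
#'
#' @param n_draws number of quasi-Bayesian coefficient draws (default 1000;
#'   fewer than 100 gives unstable percentile intervals and triggers a
#'   warning).
#' @param alpha significance level; the reported interval is the
#'   `alpha/2` to `1 - alpha/2` percentile interval of the draws, and an
#'   effect is flagged significant when that interval excludes 0.
#' @param treat,control the two exposure levels contrasted (defaults 1 and 0,
#'   the conventional unit contrast; override for other exposures).
#' @param interaction include the exposure-mediator product term in the
#'   fitted outcome model.
#' @return an object of class `mediation_options`.
#' @export
mediation_options <- function(n_draws = 1000, alpha = 0.05,
                              treat = 1, control = 0, interaction = FALSE) {
  stopifnot(is.numeric(n_draws), length(n_draws) == 1, n_draws >= 1,
            is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1,
            is.numeric(treat), is.numeric(control),
            is.logical(interaction), length(interaction) == 1)
  if (treat == control)
    stop("treat and control exposure levels must differ", call. = FALSE)
  if (n_draws < 100)
    warning("n_draws < 100: percentile intervals will be unstable",
            call. = FALSE)
  structure(list(n_draws = as.integer(n_draws), alpha = alpha,
                 treat = treat, control = control,
                 interaction = isTRUE(interaction)),
            class = "mediation_options")
}

unconverged_result <- function(options) {
  na <- NA_real_
  structure(list(acme = na, acme_lower = na, acme_upper = na, acme_sig = NA,
                 ade = na, ade_lower = na, ade_upper = na, ade_sig = NA,
                 total = na, total_lower = na, total_upper = na,
                 acme_mc_se = na, ade_mc_se = na,
                 n_draws = options$n_draws, converged = FALSE),
            class = "mediation_result")
}

#' Quasi-Bayesian counterfactual mediation estimate
#'
#' Estimates the average causal mediation effect (ACME), average direct
#' effect (ADE) and total effect of the exposure on the outcome from one
#' simulated dataset, optionally adjusting for the unmeasured confounders U.
#'
#' The algorithm: (1) fit the mediator regression `M ~ 1 + A + C (+ U)` and
#' the outcome regression `Y ~ 1 + A + M (+ A:M) + C (+ U)` with each
#' variable's declared family; (2) draw `n_draws` coefficient vectors for the
#' two fits independently from multivariate normals centred at the estimates
#' with the estimated covariances; (3) per draw, simulate potential mediators
#' `M_i(a)` for both exposure levels (normal family: linear predictor plus
#' residual noise at the fitted residual SD; Bernoulli: 0/1 at the expit of
#' the linear predictor); (4) evaluate expected potential outcomes
#' `Y_i(a, m)` from the outcome model's mean function (no outcome residual
#' noise -- the effects are averages); (5) average the counterfactual
#' contrasts over observations, averaging the mediated contrast and the
#' direct contrast over the two reference exposure levels; (6) summarise the
#' draws by their mean (point estimate) and percentile interval. Covariates
#' enter at their observed values (empirical averaging).
#'
#' @param dataset a `umed_data` dataset from [simulate_dataset()].
#' @param scenario the [mediation_scenario()] the data came from (used for
#'   the mediator and outcome families).
#' @param include_u adjust for the unmeasured confounders U?
#' @param options a [mediation_options()] object.
#' @return an object of class `mediation_result` with point estimates,
#'   percentile bounds, significance flags, Monte-Carlo standard errors
#'   (`sd(draws)`, i.e. the propagated sampling uncertainty) of ACME and ADE,
#'   and a `converged` flag. When either regression fails to converge the
#'   effects are `NA` and `converged` is `FALSE`.
#' @examples
#' sc <- mediation_scenario(mediator = mediator_model(alpha_a = 0.5),
#'                          outcome = outcome_model(beta_a = 0.3, beta_m = 0.8))
#' set.seed(11)
#' d <- simulate_dataset(sc, 500)
#' estimate_mediation(d, sc, include_u = FALSE,
#'                    options = mediation_options(n_draws = 200))
#' @export
estimate_mediation <- function(dataset, scenario, include_u = TRUE,
                               options = mediation_options()) {
  stopifnot(inherits(dataset, "umed_data"),
            inherits(scenario, "umed_scenario"),
            inherits(options, "mediation_options"))
  if (include_u && ncol(dataset$U) == 0)
    stop("include_u = TRUE but the dataset has no unmeasured confounders",
         call. = FALSE)
  n <- dataset$n
  A <- dataset$A; M <- dataset$M; Y <- dataset$Y
  covars <- dataset$C
  if (include_u) covars <- cbind(covars, dataset$U)

  xm <- cbind("(Intercept)" = rep(1, n), A = A)
  if (ncol(covars)) xm <- cbind(xm, covars)
  fit_m <- fit_model(xm, M, scenario$mediator$family)

  xy <- cbind("(Intercept)" = rep(1, n), A = A, M = M)
  if (options$interaction) xy <- cbind(xy, "A:M" = A * M)
  if (ncol(covars)) xy <- cbind(xy, covars)
  fit_y <- fit_model(xy, Y, scenario$outcome$family)

  if (!fit_m$converged || !fit_y$converged)
    return(unconverged_result(options))

  nd <- options$n_draws
  a1 <- options$treat; a0 <- options$control
  coef_m <- MASS::mvrnorm(nd, fit_m$coefficients, fit_m$covariance)
  coef_y <- MASS::mvrnorm(nd, fit_y$coefficients, fit_y$covariance)
  if (nd == 1) { coef_m <- rbind(coef_m); coef_y <- rbind(coef_y) }

  # potential mediators M_i(a): n x n_draws matrices. The two exposure
  # levels share each individual's residual draw (rank-preserving
  # counterfactuals): expectations are unchanged by linearity, while the
  # within-individual contrast M_i(treat) - M_i(control) is not polluted by
  # independent noise, which would otherwise widen the ACME draw
  # distribution beyond the estimator's sampling uncertainty.
  lp_for <- function(a) {
    x <- xm; x[, "A"] <- a
    x %*% t(coef_m)
  }
  if (scenario$mediator$family == "normal") {
    eps <- matrix(rnorm(n * nd, 0, fit_m$residual_sd), n, nd)
    m_t <- lp_for(a1) + eps
    m_c <- lp_for(a0) + eps
  } else {
    uu <- matrix(runif(n * nd), n, nd)
    m_t <- (uu < plogis(lp_for(a1))) + 0
    m_c <- (uu < plogis(lp_for(a0))) + 0
  }

  # expected potential outcomes Y_i(a, m): mean function only
  i_m <- match("M", colnames(xy))
  i_i <- if (options$interaction) match("A:M", colnames(xy)) else NA_integer_
  drop_idx <- c(i_m, if (!is.na(i_i)) i_i)
  base_for <- function(a) {
    x <- xy[, -drop_idx, drop = FALSE]; x[, "A"] <- a
    x %*% t(coef_y[, -drop_idx, drop = FALSE])
  }
  base_t <- base_for(a1)
  base_c <- base_for(a0)
  slope_for <- function(a) {
    s <- coef_y[, i_m]
    if (!is.na(i_i)) s <- s + a * coef_y[, i_i]
    s
  }
  pot_outcome <- function(base, a, m) {
    # rep(each = n) broadcasts the per-draw slope down the columns
    eta <- base + m * rep(slope_for(a), each = n)
    if (scenario$outcome$family == "bernoulli") plogis(eta) else eta
  }
  y_tt <- pot_outcome(base_t, a1, m_t)
  y_tc <- pot_outcome(base_t, a1, m_c)
  y_ct <- pot_outcome(base_c, a0, m_t)
  y_cc <- pot_outcome(base_c, a0, m_c)

  delta_t <- colMeans(y_tt - y_tc) # mediated contrast at treated exposure
  delta_c <- colMeans(y_ct - y_cc)
  zeta_t <- colMeans(y_tt - y_ct)  # direct contrast holding M at M(treat)
  zeta_c <- colMeans(y_tc - y_cc)
  acme_d <- (delta_t + delta_c) / 2
  ade_d <- (zeta_t + zeta_c) / 2
  total_d <- acme_d + ade_d

  probs <- c(options$alpha / 2, 1 - options$alpha / 2)
  ci <- function(d) unname(quantile(d, probs))
  ci_a <- ci(acme_d); ci_e <- ci(ade_d); ci_t <- ci(total_d)
  structure(list(
    acme = mean(acme_d), acme_lower = ci_a[1], acme_upper = ci_a[2],
    acme_sig = ci_a[1] > 0 || ci_a[2] < 0,
    ade = mean(ade_d), ade_lower = ci_e[1], ade_upper = ci_e[2],
    ade_sig = ci_e[1] > 0 || ci_e[2] < 0,
    total = mean(total_d), total_lower = ci_t[1], total_upper = ci_t[2],
    acme_mc_se = sd(acme_d), ade_mc_se = sd(ade_d),
    n_draws = nd, converged = TRUE), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  if (!x$converged) {
    cat("Mediation estimate: NOT converged\n")
    return(invisible(x))
  }
  fmt <- function(est, lo, hi, sig)
    sprintf("%8.4f  [%8.4f, %8.4f]%s", est, lo, hi, if (isTRUE(sig)) " *" else "")
  cat("Quasi-Bayesian mediation estimate (", x$n_draws, " draws)\n", sep = "")
  cat("  ACME (mediated): ", fmt(x$acme, x$acme_lower, x$acme_upper, x$acme_sig), "\n", sep = "")
  cat("  ADE  (direct):   ", fmt(x$ade, x$ade_lower, x$ade_upper, x$ade_sig), "\n", sep = "")
  cat("  Total effect:    ", fmt(x$total, x$total_lower, x$total_upper, NA), "\n", sep = "")
  invisible(x)
}

#' Closed-form effects for the all-linear case
#'
#' When both the mediator and the outcome follow the normal family (identity
#' links) the natural effects have closed forms. With exposure contrast
#' `a = treat`, `a* = control` and mediator mean
#' `mu_M(a) = alpha_0 + alpha_A a + alpha_C E[C] + alpha_U E[U]`:
#' \deqn{ACME = \alpha_A (a - a^*) (\beta_M + \beta_I (a + a^*)/2)}
#' \deqn{ADE = (a - a^*) (\beta_A + \beta_I (\mu_M(a) + \mu_M(a^*))/2)}
#' and the total effect is their sum. This serves as the analytic oracle for
#' the Monte-Carlo estimator; no closed form exists for logit links.
#'
#' @param scenario a [mediation_scenario()] whose mediator and outcome are
#'   both normal-family.
#' @param options a [mediation_options()] (for the exposure contrast).
#' @return an object of class `true_effects`: list with `acme`, `ade`,
#'   `total`.
#' @examples
#' sc <- mediation_scenario(mediator = mediator_model(alpha_a = 0.5),
#'                          outcome = outcome_model(beta_a = 0.3, beta_m = 0.8))
#' closed_form_effects(sc)
#' @export
closed_form_effects <- function(scenario, options = mediation_options()) {
  stopifnot(inherits(scenario, "umed_scenario"),
            inherits(options, "mediation_options"))
  me <- scenario$mediator; ou <- scenario$outcome
  if (me$family != "normal" || ou$family != "normal")
    stop("closed-form effects exist only when mediator and outcome are both ",
         "normal-family (identity links)", call. = FALSE)
  a1 <- options$treat; a0 <- options$control
  ec <- vapply(scenario$measured, confounder_mean, 0)
  eu <- vapply(scenario$unmeasured, confounder_mean, 0)
  mu_m <- function(a) me$intercept + me$coef_a * a +
    sum(me$coef_c * ec) + sum(me$coef_u * eu)
  acme <- me$coef_a * (a1 - a0) * (ou$coef_m + ou$coef_i * (a1 + a0) / 2)
  ade <- (a1 - a0) * (ou$coef_a + ou$coef_i * (mu_m(a1) + mu_m(a0)) / 2)
  structure(list(acme = acme, ade = ade, total = acme + ade),
            class = "true_effects")
}

#' @export
print.true_effects <- function(x, ...) {
  cat(sprintf("True effects (linear case): ACME = %g, ADE = %g, total = %g\n",
              x$acme, x$ade, x$total))
  invisible(x)
}
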