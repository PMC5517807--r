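# Canonical scenario builders and fake-record constructors shared by the
# tests. The canonical linear scenario is the alpha_A = 0.5, beta_A = 0.3,
# beta_M = 0.8 system with one standard-normal unmeasured confounder whose
# path coefficients (gamma_U = alpha_U = beta_U) are set by `u_effect`.

linear_scenario <- function(alpha_a = 0.5, beta_a = 0.3, beta_m = 0.8,
                            beta_i = 0, u_effect = 0,
                            unmeasured = list(normal_confounder(0, 1)),
                            measured = list()) {
  kc <- length(measured); ku <- length(unmeasured)
  mediation_scenario(
    measured = measured, unmeasured = unmeasured,
    exposure = exposure_model(gamma_c = rep(0, kc),
                              gamma_u = rep(u_effect, ku)),
    mediator = mediator_model(alpha_a = alpha_a, alpha_c = rep(0, kc),
                              alpha_u = rep(u_effect, ku)),
    outcome = outcome_model(beta_a = beta_a, beta_m = beta_m, beta_i = beta_i,
                            beta_c = rep(0, kc), beta_u = rep(u_effect, ku)))
}

# scenario without any confounders, for pure estimator-vs-oracle checks
bare_scenario <- function(alpha_a = 0.5, beta_a = 0.3, beta_m = 0.8,
                          beta_i = 0, m_family = "normal",
                          y_family = "normal") {
  mediation_scenario(
    exposure = exposure_model(),
    mediator = mediator_model(alpha_a = alpha_a, family = m_family,
                              sigma = if (m_family == "normal") 1),
    outcome = outcome_model(beta_a = beta_a, beta_m = beta_m, beta_i = beta_i,
                            family = y_family,
                            sigma = if (y_family == "normal") 1))
}

fake_result <- function(acme = 0.4, acme_sig = TRUE, ade = 0.3,
                        ade_sig = TRUE, converged = TRUE, half_width = 0.1) {
  structure(list(
    acme = acme, acme_lower = acme - half_width, acme_upper = acme + half_width,
    acme_sig = acme_sig,
    ade = ade, ade_lower = ade - half_width, ade_upper = ade + half_width,
    ade_sig = ade_sig,
    total = acme + ade, total_lower = NA_real_, total_upper = NA_real_,
    acme_mc_se = half_width / 2, ade_mc_se = half_width / 2,
    n_draws = 100L, converged = converged), class = "mediation_result")
}

fake_record <- function(iteration, without_u, with_u, master_seed = 1L) {
  cm <- diag(1, 3)
  dimnames(cm) <- list(c("A", "M", "Y"), c("A", "M", "Y"))
  structure(list(iteration = as.integer(iteration),
                 master_seed = as.integer(master_seed),
                 without_u = without_u, with_u = with_u,
                 correlations = cm), class = "paired_record")
}

# model-implied covariance of (A, M, Y, C..., U...) for the all-linear case:
# every variable is a linear combination of the independent basis
# (C..., U..., eps_A, eps_M, eps_Y), so covariances follow from the
# coefficient vectors and basis variances alone.
linear_covariance_oracle <- function(scenario) {
  spec_var <- function(s) if (s$kind == "normal") s$variance
                          else s$prob * (1 - s$prob)
  kc <- length(scenario$measured); ku <- length(scenario$unmeasured)
  basis_var <- c(vapply(scenario$measured, spec_var, 0),
                 vapply(scenario$unmeasured, spec_var, 0),
                 scenario$exposure$sigma^2, scenario$mediator$sigma^2,
                 scenario$outcome$sigma^2)
  nb <- kc + ku + 3
  unit <- function(i) { v <- numeric(nb); v[i] <- 1; v }
  ex <- scenario$exposure; me <- scenario$mediator; ou <- scenario$outcome
  a_vec <- c(ex$coef_c, ex$coef_u, 1, 0, 0)
  m_vec <- me$coef_a * a_vec + c(me$coef_c, me$coef_u, 0, 1, 0)
  y_vec <- ou$coef_a * a_vec + ou$coef_m * m_vec +
    c(ou$coef_c, ou$coef_u, 0, 0, 1)
  vecs <- c(list(A = a_vec, M = m_vec, Y = y_vec),
            lapply(seq_len(kc), function(j) unit(j)),
            lapply(seq_len(ku), function(j) unit(kc + j)))
  names(vecs) <- c("A", "M", "Y",
                   confounder_labels(scenario$measured),
                   confounder_labels(scenario$unmeasured))
  k <- length(vecs)
  out <- matrix(0, k, k, dimnames = list(names(vecs), names(vecs)))
  for (i in seq_len(k))
    for (j in seq_len(k))
      out[i, j] <- sum(vecs[[i]] * vecs[[j]] * basis_var)
  out
}

confounder_labels <- function(specs) vapply(specs, `[[`, "", "label")
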