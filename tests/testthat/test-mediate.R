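test_that("closed-form linear effects follow the product-of-coefficients algebra", {
  o <- mediation_options()
  e1 <- closed_form_effects(bare_scenario(alpha_a = 0.5, beta_m = 0.8,
                                          beta_a = 0.3), o)
  expect_equal(e1$acme, 0.40)
  expect_equal(e1$ade, 0.30)
  expect_equal(e1$total, 0.70)

  # interaction case: ACME = 0.5 (0.8 + 0.2/2), ADE = 0.3 + 0.2 (0 + 0.5)/2
  e2 <- closed_form_effects(bare_scenario(alpha_a = 0.5, beta_m = 0.8,
                                          beta_a = 0.3, beta_i = 0.2), o)
  expect_equal(e2$acme, 0.45)
  expect_equal(e2$ade, 0.35)

  e3 <- closed_form_effects(bare_scenario(alpha_a = 0), o)
  expect_equal(e3$acme, 0)

  # confounder means shift mu_M and hence the interaction part of the ADE
  sc <- mediation_scenario(
    measured = list(normal_confounder(mean = 2, variance = 1)),
    exposure = exposure_model(gamma_c = 0),
    mediator = mediator_model(alpha_a = 0.5, alpha_c = 1),
    outcome = outcome_model(beta_a = 0.3, beta_m = 0.8, beta_i = 0.2,
                            beta_c = 0))
  e4 <- closed_form_effects(sc, o)
  expect_equal(e4$acme, 0.45)
  expect_equal(e4$ade, 0.3 + 0.2 * (2 + 2.5) / 2)

  expect_error(closed_form_effects(bare_scenario(y_family = "bernoulli"), o),
               "normal")
})

test_that("the Monte-Carlo estimator recovers the linear oracle", {
  cases <- list(list(alpha_a = 0.5, beta_m = 0.8, beta_a = 0.3, beta_i = 0),
                list(alpha_a = 1.0, beta_m = 0.4, beta_a = 0.0, beta_i = 0),
                list(alpha_a = 0.5, beta_m = 0.8, beta_a = 0.3, beta_i = 0.4),
                list(alpha_a = 0.0, beta_m = 0.8, beta_a = 0.5, beta_i = 0))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    sc <- bare_scenario(alpha_a = cs$alpha_a, beta_m = cs$beta_m,
                        beta_a = cs$beta_a, beta_i = cs$beta_i)
    o <- mediation_options(n_draws = 500, interaction = cs$beta_i != 0)
    truth <- closed_form_effects(sc, o)
    set.seed(400 + i)
    d <- simulate_dataset(sc, 2000)
    est <- estimate_mediation(d, sc, include_u = FALSE, options = o)
    expect_lt(abs(est$acme - truth$acme), 3 * est$acme_mc_se)
    expect_lt(abs(est$ade - truth$ade), 3 * est$ade_mc_se)
    expect_true(est$acme_lower <= est$acme && est$acme <= est$acme_upper)
    expect_true(est$ade_lower <= est$ade && est$ade <= est$ade_upper)
  }
})

test_that("the reported total is exactly the per-draw ACME + ADE average", {
  sc <- bare_scenario(beta_i = 0.3)
  set.seed(410)
  d <- simulate_dataset(sc, 1000)
  est <- estimate_mediation(d, sc, FALSE,
                            mediation_options(n_draws = 300, interaction = TRUE))
  expect_equal(est$total, est$acme + est$ade, tolerance = 1e-12)
})

test_that("a flat binary outcome model yields null effects", {
  sc <- bare_scenario(alpha_a = 0.5, beta_a = 0, beta_m = 0,
                      y_family = "bernoulli")
  set.seed(420)
  d <- simulate_dataset(sc, 2000)
  est <- estimate_mediation(d, sc, FALSE, mediation_options(n_draws = 500))
  expect_lt(abs(est$acme), 3 * est$acme_mc_se)
  expect_lt(abs(est$ade), 3 * est$ade_mc_se)
})

test_that("binary mediators are handled through the logit mechanism", {
  sc <- bare_scenario(alpha_a = 1, beta_m = 0.8, beta_a = 0.3,
                      m_family = "bernoulli")
  set.seed(430)
  d <- simulate_dataset(sc, 3000)
  est <- estimate_mediation(d, sc, FALSE, mediation_options(n_draws = 500))
  expect_true(est$converged)
  # true ACME for a binary mediator on an identity-link outcome:
  # beta_M * (P(M=1 | a=1) - P(M=1 | a=0)) = 0.8 * (expit(1) - expit(0))
  truth <- 0.8 * (plogis(1) - plogis(0))
  expect_lt(abs(est$acme - truth), 4 * est$acme_mc_se)
  expect_equal(est$total, est$acme + est$ade, tolerance = 1e-12)
})

test_that("including an unneeded interaction term leaves estimates stable", {
  sc <- bare_scenario(beta_i = 0)
  set.seed(440)
  d <- simulate_dataset(sc, 2000)
  set.seed(441)
  e_plain <- estimate_mediation(d, sc, FALSE, mediation_options(n_draws = 500))
  set.seed(442)
  e_int <- estimate_mediation(d, sc, FALSE,
                              mediation_options(n_draws = 500,
                                                interaction = TRUE))
  comb <- sqrt(e_plain$acme_mc_se^2 + e_int$acme_mc_se^2)
  expect_lt(abs(e_plain$acme - e_int$acme), 3 * comb)
  comb_d <- sqrt(e_plain$ade_mc_se^2 + e_int$ade_mc_se^2)
  expect_lt(abs(e_plain$ade - e_int$ade), 3 * comb_d)
})

test_that("covariate column order does not change the estimates", {
  sc <- mediation_scenario(
    measured = list(normal_confounder(0, 1, label = "age"),
                    bernoulli_confounder(0.4, label = "sex")),
    exposure = exposure_model(gamma_c = c(0.5, 0.3)),
    mediator = mediator_model(alpha_a = 0.5, alpha_c = c(0.4, 0.2)),
    outcome = outcome_model(beta_a = 0.3, beta_m = 0.8, beta_c = c(0.2, 0.6)))
  set.seed(450)
  d <- simulate_dataset(sc, 800)
  d_swap <- d
  d_swap$C <- d$C[, c(2, 1)]
  o <- mediation_options(n_draws = 1000)
  set.seed(451); e1 <- estimate_mediation(d, sc, FALSE, o)
  set.seed(451); e2 <- estimate_mediation(d_swap, sc, FALSE, o)
  # the fitted regressions are permutation-invariant; the coefficient draws
  # are not bitwise so, hence agreement is at the draw-mean noise level
  draw_noise <- function(a, b) 3 * sqrt((a^2 + b^2) / o$n_draws)
  expect_lt(abs(e1$acme - e2$acme),
            draw_noise(e1$acme_mc_se, e2$acme_mc_se))
  expect_lt(abs(e1$ade - e2$ade), draw_noise(e1$ade_mc_se, e2$ade_mc_se))
})

test_that("estimation is reproducible and validates its inputs", {
  sc <- linear_scenario(u_effect = 1)
  set.seed(460)
  d <- simulate_dataset(sc, 300)
  o <- mediation_options(n_draws = 200)
  set.seed(1); e1 <- estimate_mediation(d, sc, TRUE, o)
  set.seed(1); e2 <- estimate_mediation(d, sc, TRUE, o)
  expect_identical(e1, e2)

  d_no_u <- simulate_dataset(bare_scenario(), 300)
  expect_error(estimate_mediation(d_no_u, bare_scenario(), TRUE, o),
               "unmeasured")
  expect_error(mediation_options(treat = 1, control = 1), "differ")
  expect_warning(mediation_options(n_draws = 50), "unstable")
})
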