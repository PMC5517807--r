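#' Confounder distribution specifications
#'
#' A confounder (measured C or unmeasured U) is drawn i.i.d. from either a
#' normal distribution with given mean and variance or a Bernoulli
#' distribution with given success probability. All confounders in a scenario
#' are generated mutually independently; in particular there is no
#' cross-correlation between measured and unmeasured confounders (a stated
#' assumption of the framework, reasonable e.g. for orthogonal genetic
#' principal components).
#'
#' @param mean mean of the normal confounder.
#' @param variance variance of the normal confounder (>= 0).
#' @param prob success probability of the Bernoulli confounder, in `[0, 1]`.
#' @param label optional short name used in column headers and correlation
#'   matrices; defaults to `C1`, `C2`, ... / `U1`, `U2`, ... when the scenario
#'   is assembled. Must contain only letters, digits and dots.
#' @return an object of class `confounder_spec`.
#' @examples
#' normal_confounder(0, 0.001)   # a weak ancestry principal component
#' bernoulli_confounder(0.5, label = "sex")
#' @export
normal_confounder <- function(mean = 0, variance = 1, label = NULL) {
  stopifnot(is.numeric(mean), length(mean) == 1, is.finite(mean),
            is.numeric(variance), length(variance) == 1, is.finite(variance))
  if (variance < 0)
    stop("confounder '", label %||% "?", "': variance must be >= 0", call. = FALSE)
  check_label(label)
  structure(list(kind = "normal", mean = mean, variance = variance,
                 prob = NULL, label = label),
            class = "confounder_spec")
}

#' @rdname normal_confounder
#' @export
bernoulli_confounder <- function(prob, label = NULL) {
  stopifnot(is.numeric(prob), length(prob) == 1, is.finite(prob))
  if (prob < 0 || prob > 1)
    stop("confounder '", label %||% "?", "': prob must be in [0, 1]", call. = FALSE)
  check_label(label)
  structure(list(kind = "bernoulli", mean = NULL, variance = NULL,
                 prob = prob, label = label),
            class = "confounder_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_label <- function(label) {
  if (is.null(label)) return(invisible(NULL))
  stopifnot(is.character(label), length(label) == 1)
  if (!grepl("^[A-Za-z][A-Za-z0-9.]*$", label))
    stop("label '", label, "' must start with a letter and contain only ",
         "letters, digits and dots", call. = FALSE)
  invisible(NULL)
}

check_family <- function(family, sigma, what) {
  family <- match.arg(family, c("normal", "bernoulli"))
  if (family == "normal") {
    sigma <- sigma %||% 1
    stopifnot(is.numeric(sigma), length(sigma) == 1, is.finite(sigma))
    if (sigma <= 0)
      stop(what, ": sigma must be > 0 for the normal family", call. = FALSE)
  } else {
    if (!is.null(sigma))
      stop(what, ": sigma applies only to the normal family", call. = FALSE)
    sigma <- NULL
  }
  list(family = family, sigma = sigma)
}

check_coef <- function(x, what) {
  stopifnot(is.numeric(x))
  if (length(x) && any(!is.finite(x)))
    stop(what, ": coefficients must be finite", call. = FALSE)
  as.numeric(x)
}

#' Structural models for exposure, mediator and outcome
#'
#' Each variable follows a generalised linear structural equation. On the
#' identity link (normal family) the variable equals its linear predictor plus
#' independent normal noise with standard deviation `sigma`; on the logit link
#' (Bernoulli family) the variable is a 0/1 draw with success probability
#' `plogis(linear predictor)`. The linear predictors are
#' \deqn{E[A] = \gamma_0 + \gamma_C C + \gamma_U U}
#' \deqn{E[M] = \alpha_0 + \alpha_A A + \alpha_C C + \alpha_U U}
#' \deqn{E[Y] = \beta_0 + \beta_A A + \beta_M M + \beta_I A M
#'   + \beta_C C + \beta_U U}
#' where the confounder coefficient vectors match the confounder lists of the
#' enclosing [mediation_scenario()].
#'
#' @param gamma0,alpha0,beta0 intercepts.
#' @param gamma_c,gamma_u,alpha_c,alpha_u,beta_c,beta_u coefficient vectors
#'   for the measured (C) and unmeasured (U) confounders; lengths must equal
#'   the number of confounders of each kind in the scenario.
#' @param alpha_a,beta_a coefficients of the exposure on the mediator and the
#'   outcome.
#' @param beta_m coefficient of the mediator on the outcome.
#' @param beta_i exposure-mediator interaction coefficient on the outcome
#'   (`0` for no interaction).
#' @param family `"normal"` (identity link) or `"bernoulli"` (logit link).
#' @param sigma residual standard deviation; normal family only, default 1.
#' @return an object of class `exposure_model`, `mediator_model` or
#'   `outcome_model`.
#' @examples
#' exposure_model(gamma0 = 0, gamma_u = 1)
#' mediator_model(alpha_a = 0.5, alpha_u = 1)
#' outcome_model(beta_a = 0.3, beta_m = 0.8, beta_u = 1)
#' @export
exposure_model <- function(gamma0 = 0, gamma_c = numeric(), gamma_u = numeric(),
                           family = c("normal", "bernoulli"), sigma = NULL) {
  fs <- check_family(family, sigma, "exposure model")
  structure(list(intercept = gamma0,
                 coef_c = check_coef(gamma_c, "exposure model gamma_c"),
                 coef_u = check_coef(gamma_u, "exposure model gamma_u"),
                 family = fs$family, sigma = fs$sigma),
            class = "exposure_model")
}

#' @rdname exposure_model
#' @export
mediator_model <- function(alpha0 = 0, alpha_a = 0, alpha_c = numeric(),
                           alpha_u = numeric(),
                           family = c("normal", "bernoulli"), sigma = NULL) {
  fs <- check_family(family, sigma, "mediator model")
  stopifnot(is.numeric(alpha_a), length(alpha_a) == 1, is.finite(alpha_a))
  structure(list(intercept = alpha0, coef_a = alpha_a,
                 coef_c = check_coef(alpha_c, "mediator model alpha_c"),
                 coef_u = check_coef(alpha_u, "mediator model alpha_u"),
                 family = fs$family, sigma = fs$sigma),
            class = "mediator_model")
}

#' @rdname exposure_model
#' @export
outcome_model <- function(beta0 = 0, beta_a = 0, beta_m = 0, beta_i = 0,
                          beta_c = numeric(), beta_u = numeric(),
                          family = c("normal", "bernoulli"), sigma = NULL) {
  fs <- check_family(family, sigma, "outcome model")
  stopifnot(is.numeric(beta_a), is.numeric(beta_m), is.numeric(beta_i))
  structure(list(intercept = beta0, coef_a = beta_a, coef_m = beta_m,
                 coef_i = beta_i,
                 coef_c = check_coef(beta_c, "outcome model beta_c"),
                 coef_u = check_coef(beta_u, "outcome model beta_u"),
                 family = fs$family, sigma = fs$sigma),
            class = "outcome_model")
}

#' Assemble a full generative mediation scenario
#'
#' Binds the confounder specifications and the three structural models into
#' one validated object. Validation checks that every confounder coefficient
#' vector has exactly one entry per confounder of the matching kind, and
#' assigns default labels `C1, C2, ...` and `U1, U2, ...` to unlabelled
#' confounders.
#'
#' @param measured list of [normal_confounder()] / [bernoulli_confounder()]
#'   specifications for the measured confounders C (may be empty).
#' @param unmeasured list of confounder specifications for the unmeasured
#'   confounders U (may be empty).
#' @param exposure an [exposure_model()].
#' @param mediator a [mediator_model()].
#' @param outcome an [outcome_model()].
#' @return an object of class `umed_scenario`.
#' @examples
#' sc <- mediation_scenario(
#'   unmeasured = list(normal_confounder(0, 1)),
#'   exposure   = exposure_model(gamma_u = 1),
#'   mediator   = mediator_model(alpha_a = 0.5, alpha_u = 1),
#'   outcome    = outcome_model(beta_a = 0.3, beta_m = 0.8, beta_u = 1)
#' )
#' sc
#' @export
mediation_scenario <- function(measured = list(), unmeasured = list(),
                               exposure = exposure_model(),
                               mediator = mediator_model(),
                               outcome = outcome_model()) {
  stopifnot(is.list(measured), is.list(unmeasured),
            inherits(exposure, "exposure_model"),
            inherits(mediator, "mediator_model"),
            inherits(outcome, "outcome_model"))
  measured <- label_confounders(measured, "C")
  unmeasured <- label_confounders(unmeasured, "U")
  kc <- length(measured); ku <- length(unmeasured)
  check_len <- function(v, k, what) {
    if (length(v) != k)
      stop(what, " has length ", length(v), " but the scenario has ", k,
           " confounder(s) of that kind", call. = FALSE)
  }
  check_len(exposure$coef_c, kc, "gamma_c"); check_len(exposure$coef_u, ku, "gamma_u")
  check_len(mediator$coef_c, kc, "alpha_c"); check_len(mediator$coef_u, ku, "alpha_u")
  check_len(outcome$coef_c, kc, "beta_c"); check_len(outcome$coef_u, ku, "beta_u")
  labs <- c(vapply(measured, `[[`, "", "label"),
            vapply(unmeasured, `[[`, "", "label"))
  if (anyDuplicated(c("A", "M", "Y", labs)))
    stop("confounder labels must be unique and distinct from A, M, Y",
         call. = FALSE)
  structure(list(measured = measured, unmeasured = unmeasured,
                 exposure = exposure, mediator = mediator, outcome = outcome),
            class = "umed_scenario")
}

label_confounders <- function(specs, prefix) {
  for (j in seq_along(specs)) {
    if (!inherits(specs[[j]], "confounder_spec"))
      stop(prefix, " confounder ", j, " is not a confounder specification",
           call. = FALSE)
    if (is.null(specs[[j]]$label))
      specs[[j]]$label <- paste0(prefix, j)
  }
  specs
}

#' @export
print.umed_scenario <- function(x, ...) {
  fam <- function(m) if (m$family == "normal")
    sprintf("normal (sigma = %g)", m$sigma) else "bernoulli (logit link)"
  cat("Mediation scenario\n")
  cat(sprintf("  exposure A: %s, intercept %g\n", fam(x$exposure), x$exposure$intercept))
  cat(sprintf("  mediator M: %s, alpha_A = %g\n", fam(x$mediator), x$mediator$coef_a))
  cat(sprintf("  outcome  Y: %s, beta_A = %g, beta_M = %g, beta_I = %g\n",
              fam(x$outcome), x$outcome$coef_a, x$outcome$coef_m, x$outcome$coef_i))
  dsc <- function(s) {
    if (s$kind == "normal") sprintf("%s ~ N(%g, %g)", s$label, s$mean, s$variance)
    else sprintf("%s ~ Bern(%g)", s$label, s$prob)
  }
  cat(sprintf("  measured confounders:   %s\n",
              if (length(x$measured)) paste(vapply(x$measured, dsc, ""), collapse = ", ")
              else "none"))
  cat(sprintf("  unmeasured confounders: %s\n",
              if (length(x$unmeasured)) paste(vapply(x$unmeasured, dsc, ""), collapse = ", ")
              else "none"))
  invisible(x)
}

confounder_labels <- function(specs) vapply(specs, `[[`, "", "label")

confounder_mean <- function(s) if (s$kind == "normal") s$mean else s$prob
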