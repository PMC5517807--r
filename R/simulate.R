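#' Draw a matrix of independent confounders
#'
#' Draws `n` i.i.d. realisations of each confounder specification; columns are
#' mutually independent by construction.
#'
#' @param specs list of confounder specifications
#'   ([normal_confounder()] / [bernoulli_confounder()]).
#' @param n number of rows (>= 1).
#' @return an `n x length(specs)` numeric matrix; column names are the
#'   confounder labels when set.
#' @examples
#' set.seed(1)
#' colMeans(draw_confounders(list(normal_confounder(0, 0.001)), 1000))
#' @export
draw_confounders <- function(specs, n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  out <- matrix(0, nrow = n, ncol = length(specs))
  for (j in seq_along(specs)) {
    s <- specs[[j]]
    if (!inherits(s, "confounder_spec"))
      stop("confounder ", j, " is not a confounder specification", call. = FALSE)
    out[, j] <- switch(s$kind,
      normal    = rnorm(n, mean = s$mean, sd = sqrt(s$variance)),
      bernoulli = rbinom(n, 1L, s$prob),
      stop("confounder '", s$label %||% j, "': unknown kind '", s$kind, "'",
           call. = FALSE)
    )
  }
  if (length(specs))
    colnames(out) <- vapply(seq_along(specs), function(j)
      specs[[j]]$label %||% paste0("V", j), "")
  out
}

#' Draw a structural variable from its linear predictor
#'
#' Applies the family's random mechanism to a linear predictor: the normal
#' family (identity link) adds i.i.d. normal noise with standard deviation
#' `sigma`; the Bernoulli family (logit link) draws 0/1 with success
#' probability `plogis(linear_predictor)` elementwise.
#'
#' @param linear_predictor numeric vector of linear-predictor values.
#' @param family `"normal"` or `"bernoulli"`.
#' @param sigma residual standard deviation (normal family only).
#' @param what label used in error messages to identify the generating model.
#' @return numeric vector of the same length as `linear_predictor`.
#' @export
draw_structural <- function(linear_predictor, family = c("normal", "bernoulli"),
                            sigma = NULL, what = "structural variable") {
  family <- match.arg(family)
  if (any(!is.finite(linear_predictor)))
    stop("non-finite linear predictor while generating ", what, call. = FALSE)
  n <- length(linear_predictor)
  if (family == "normal") {
    if (is.null(sigma))
      stop(what, ": sigma is required for the normal family", call. = FALSE)
    linear_predictor + rnorm(n, 0, sigma)
  } else {
    as.numeric(rbinom(n, 1L, plogis(linear_predictor)))
  }
}

#' Simulate one dataset from a mediation scenario
#'
#' Generates, in order, the confounders C and U, then the exposure A, the
#' mediator M and the outcome Y from their structural equations (see
#' [exposure_model()]), each through [draw_structural()] with its declared
#' family.
#'
#' @param scenario a [mediation_scenario()].
#' @param n sample size (>= 1). Sample sizes of 30 or less trigger a warning:
#'   the downstream regression inference is asymptotic.
#' @return an object of class `umed_data`: a list with numeric vectors `A`,
#'   `M`, `Y` and matrices `C` (`n x #C`) and `U` (`n x #U`).
#' @examples
#' sc <- mediation_scenario(mediator = mediator_model(alpha_a = 0.5),
#'                          outcome = outcome_model(beta_a = 0.3, beta_m = 0.8))
#' set.seed(7)
#' d <- simulate_dataset(sc, 100)
#' head(as.data.frame(d))
#' @export
simulate_dataset <- function(scenario, n) {
  stopifnot(inherits(scenario, "umed_scenario"),
            is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  if (n <= 30)
    warning("sample size n = ", n, " <= 30: the regression models rely on ",
            "asymptotic inference and small samples may violate it",
            call. = FALSE)
  C <- draw_confounders(scenario$measured, n)
  U <- draw_confounders(scenario$unmeasured, n)
  ex <- scenario$exposure; me <- scenario$mediator; ou <- scenario$outcome
  lp_a <- ex$intercept + drop(C %*% ex$coef_c) + drop(U %*% ex$coef_u)
  A <- draw_structural(lp_a, ex$family, ex$sigma, "the exposure model")
  lp_m <- me$intercept + me$coef_a * A +
    drop(C %*% me$coef_c) + drop(U %*% me$coef_u)
  M <- draw_structural(lp_m, me$family, me$sigma, "the mediator model")
  lp_y <- ou$intercept + ou$coef_a * A + ou$coef_m * M + ou$coef_i * (A * M) +
    drop(C %*% ou$coef_c) + drop(U %*% ou$coef_u)
  Y <- draw_structural(lp_y, ou$family, ou$sigma, "the outcome model")
  structure(list(A = A, M = M, Y = Y, C = C, U = U, n = n),
            class = "umed_data")
}

#' @export
as.data.frame.umed_data <- function(x, ...) {
  out <- data.frame(A = x$A, M = x$M, Y = x$Y)
  if (ncol(x$C)) out <- cbind(out, as.data.frame(x$C))
  if (ncol(x$U)) out <- cbind(out, as.data.frame(x$U))
  out
}

#' @export
print.umed_data <- function(x, ...) {
  cat(sprintf("Simulated mediation dataset: n = %d, %d measured and %d unmeasured confounder(s)\n",
              x$n, ncol(x$C), ncol(x$U)))
  invisible(x)
}

#' Pearson correlation matrix of all model variables
#'
#' Correlations over the columns A, M, Y, C..., U... of a simulated dataset.
#' A zero-variance column yields `NA` in its row and column (reported as
#' undefined rather than silently zero).
#'
#' @param dataset a `umed_data` object (or a data frame of its columns).
#' @return a symmetric labelled correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(dataset) {
  df <- if (inherits(dataset, "umed_data")) as.data.frame(dataset)
        else as.data.frame(dataset)
  x <- as.matrix(df)
  stopifnot(nrow(x) >= 3)
  sds <- apply(x, 2, sd)
  r <- suppressWarnings(cor(x))
  degenerate <- sds == 0 | !is.finite(sds)
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  diag(r)[!degenerate] <- 1
  r
}
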