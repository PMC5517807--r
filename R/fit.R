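#' Fit a regression model on an explicit design matrix
#'
#' Thin wrapper around the base least-squares and IRLS machinery that returns
#' exactly what the quasi-Bayesian mediation step needs: coefficient
#' estimates, their estimated sampling covariance, the residual standard
#' deviation (normal family) and a convergence flag.
#'
#' @param design `n x p` numeric design matrix with column names (include an
#'   intercept column explicitly).
#' @param response numeric response vector of length `n`; must be 0/1 for the
#'   Bernoulli family.
#' @param family `"normal"` (ordinary least squares, identity link) or
#'   `"bernoulli"` (maximum-likelihood logistic regression).
#' @return an object of class `fitted_model`: list with `coefficients`
#'   (named), `covariance`, `residual_sd` (`NULL` for Bernoulli), `family`,
#'   `term_order` and `converged`.
#' @examples
#' x <- cbind("(Intercept)" = 1, x = 1:10)
#' fit_model(x, 2 + 3 * (1:10), "normal")$coefficients
#' @export
fit_model <- function(design, response, family = c("normal", "bernoulli")) {
  family <- match.arg(family)
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  stopifnot(length(response) == n, is.numeric(response))
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(p))
  if (n <= p)
    stop("need more observations (", n, ") than model terms (", p, ")",
         call. = FALSE)
  qrd <- qr(design)
  if (qrd$rank < p) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (family == "normal") {
    fit <- lm.fit(design, response)
    coefs <- fit$coefficients
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - p)
    covb <- sigma2 * chol2inv(chol(crossprod(design)))
    dimnames(covb) <- list(colnames(design), colnames(design))
    out <- list(coefficients = coefs, covariance = covb,
                residual_sd = sqrt(sigma2), family = family,
                term_order = colnames(design), converged = TRUE)
  } else {
    if (!all(response %in% c(0, 1)))
      stop("Bernoulli-family response must contain only 0 and 1", call. = FALSE)
    boundary <- FALSE
    fit <- withCallingHandlers(
      glm.fit(design, response, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          boundary <<- TRUE
        invokeRestart("muffleWarning")
      })
    coefs <- fit$coefficients
    names(coefs) <- colnames(design)
    info <- crossprod(design * sqrt(fit$weights))
    covb <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    converged <- isTRUE(fit$converged) && !boundary && !is.null(covb)
    if (is.null(covb)) covb <- matrix(NA_real_, p, p)
    dimnames(covb) <- list(colnames(design), colnames(design))
    out <- list(coefficients = coefs, covariance = covb,
                residual_sd = NULL, family = family,
                term_order = colnames(design), converged = converged)
  }
  class(out) <- "fitted_model"
  out
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("%s-family fit (%s)\n", x$family,
              if (x$converged) "converged" else "NOT converged"))
  print(x$coefficients)
  invisible(x)
}
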