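#' Load a study configuration from YAML
#'
#' Reads one documented YAML dialect describing a complete study: the
#' generative scenario, sample size, number of iterations, master seed,
#' estimator options and an optional sweep grid. The file is validated
#' completely before any computation; unknown keys are rejected with the
#' offending key named, and defaults (`n_draws = 1000`, `alpha = 0.05`,
#' `treat = 1`, `control = 0`, `interaction = FALSE`, sigmas = 1) are applied.
#'
#' Top-level keys: `n`, `n_sim`, `seed` (required); `measured_confounders`,
#' `unmeasured_confounders` (lists of `{kind, mean, variance | prob, label}`),
#' `exposure` (`{family, gamma0, gamma_c, gamma_u, sigma}`), `mediator`
#' (`{family, alpha0, alpha_a, alpha_c, alpha_u, sigma}`), `outcome`
#' (`{family, beta0, beta_a, beta_m, beta_i, beta_c, beta_u, sigma}`),
#' `options` (`{n_draws, alpha, treat, control, interaction}`), `sweep_grid`,
#' `output_prefix`.
#'
#' @param path path to a YAML configuration file.
#' @return an object of class `umed_config`: list with `scenario`, `n`,
#'   `n_sim`, `master_seed`, `options`, `sweep_grid` (or `NULL`),
#'   `output_prefix` (or `NULL`).
#' @seealso [write_config()] for the inverse.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  # YAML 1.1 would read the bare key `n` as a boolean; keep it literal while
  # still parsing true/false values as logicals
  handlers <- list(
    "bool#no" = function(x) if (tolower(x) == "n") "n" else FALSE,
    "bool#yes" = function(x) if (tolower(x) == "y") "y" else TRUE)
  raw <- yaml::read_yaml(path, handlers = handlers)
  build_config(raw)
}

build_config <- function(raw) {
  known <- c("n", "n_sim", "seed", "measured_confounders",
             "unmeasured_confounders", "exposure", "mediator", "outcome",
             "options", "sweep_grid", "output_prefix")
  check_keys(raw, known, "config")
  for (key in c("n", "n_sim", "seed", "exposure", "mediator", "outcome"))
    if (is.null(raw[[key]]))
      stop("config is missing required key '", key, "'", call. = FALSE)
  num1 <- function(key) {
    v <- raw[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("config key '", key, "' must be a single number", call. = FALSE)
    v
  }
  measured <- parse_confounders(raw$measured_confounders,
                                "measured_confounders")
  unmeasured <- parse_confounders(raw$unmeasured_confounders,
                                  "unmeasured_confounders")

  ex <- raw$exposure
  check_keys(ex, c("family", "gamma0", "gamma_c", "gamma_u", "sigma"), "exposure")
  exposure <- exposure_model(gamma0 = ex$gamma0 %||% 0,
                             gamma_c = as.numeric(ex$gamma_c %||% numeric()),
                             gamma_u = as.numeric(ex$gamma_u %||% numeric()),
                             family = ex$family %||% "normal",
                             sigma = ex$sigma)
  me <- raw$mediator
  check_keys(me, c("family", "alpha0", "alpha_a", "alpha_c", "alpha_u", "sigma"),
             "mediator")
  mediator <- mediator_model(alpha0 = me$alpha0 %||% 0,
                             alpha_a = me$alpha_a %||% 0,
                             alpha_c = as.numeric(me$alpha_c %||% numeric()),
                             alpha_u = as.numeric(me$alpha_u %||% numeric()),
                             family = me$family %||% "normal",
                             sigma = me$sigma)
  ou <- raw$outcome
  check_keys(ou, c("family", "beta0", "beta_a", "beta_m", "beta_i", "beta_c",
                   "beta_u", "sigma"), "outcome")
  outcome <- outcome_model(beta0 = ou$beta0 %||% 0,
                           beta_a = ou$beta_a %||% 0,
                           beta_m = ou$beta_m %||% 0,
                           beta_i = ou$beta_i %||% 0,
                           beta_c = as.numeric(ou$beta_c %||% numeric()),
                           beta_u = as.numeric(ou$beta_u %||% numeric()),
                           family = ou$family %||% "normal",
                           sigma = ou$sigma)
  scenario <- mediation_scenario(measured, unmeasured, exposure, mediator,
                                 outcome)
  op <- raw$options %||% list()
  check_keys(op, c("n_draws", "alpha", "treat", "control", "interaction"),
             "options")
  options <- mediation_options(n_draws = op$n_draws %||% 1000,
                               alpha = op$alpha %||% 0.05,
                               treat = op$treat %||% 1,
                               control = op$control %||% 0,
                               interaction = op$interaction %||% FALSE)
  grid <- if (!is.null(raw$sweep_grid)) as.numeric(raw$sweep_grid)
  structure(list(scenario = scenario, n = as.integer(num1("n")),
                 n_sim = as.integer(num1("n_sim")),
                 master_seed = as.integer(num1("seed")),
                 options = options, sweep_grid = grid,
                 output_prefix = raw$output_prefix),
            class = "umed_config")
}

check_keys <- function(x, known, where) {
  if (is.null(x)) return(invisible(NULL))
  if (!is.list(x)) stop("config section '", where, "' must be a mapping",
                        call. = FALSE)
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown key '", where, ".", extra[1], "' in config", call. = FALSE)
  invisible(NULL)
}

parse_confounders <- function(lst, where) {
  if (is.null(lst)) return(list())
  if (!is.list(lst)) stop("'", where, "' must be a list of mappings",
                          call. = FALSE)
  lapply(seq_along(lst), function(j) {
    s <- lst[[j]]
    here <- paste0(where, "[", j, "]")
    check_keys(s, c("kind", "mean", "variance", "prob", "label"), here)
    kind <- s$kind %||% stop("'", here, "' is missing 'kind'", call. = FALSE)
    if (kind == "normal") {
      if (!is.null(s$prob))
        stop("'", here, "': 'prob' is not valid for a normal confounder",
             call. = FALSE)
      normal_confounder(s$mean %||% 0, s$variance %||% 1, s$label)
    } else if (kind == "bernoulli") {
      if (!is.null(s$mean) || !is.null(s$variance))
        stop("'", here, "': mean/variance are not valid for a Bernoulli ",
             "confounder", call. = FALSE)
      if (is.null(s$prob)) stop("'", here, "' is missing 'prob'", call. = FALSE)
      bernoulli_confounder(s$prob, s$label)
    } else stop("'", here, "': kind must be 'normal' or 'bernoulli'",
                call. = FALSE)
  })
}

#' Write a study configuration back to YAML
#'
#' Inverse of [load_config()]: the written file loads back to an equal
#' configuration (round-trip property).
#'
#' @param config a `umed_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "umed_config"))
  sc <- config$scenario
  conf_list <- function(specs) lapply(specs, function(s) {
    if (s$kind == "normal")
      list(kind = "normal", mean = s$mean, variance = s$variance,
           label = s$label)
    else list(kind = "bernoulli", prob = s$prob, label = s$label)
  })
  model_sigma <- function(m) if (m$family == "normal") m$sigma else NULL
  out <- list(
    n = config$n, n_sim = config$n_sim, seed = config$master_seed,
    measured_confounders = conf_list(sc$measured),
    unmeasured_confounders = conf_list(sc$unmeasured),
    exposure = drop_null(list(family = sc$exposure$family,
                    gamma0 = sc$exposure$intercept,
                    gamma_c = sc$exposure$coef_c, gamma_u = sc$exposure$coef_u,
                    sigma = model_sigma(sc$exposure))),
    mediator = drop_null(list(family = sc$mediator$family,
                    alpha0 = sc$mediator$intercept,
                    alpha_a = sc$mediator$coef_a,
                    alpha_c = sc$mediator$coef_c, alpha_u = sc$mediator$coef_u,
                    sigma = model_sigma(sc$mediator))),
    outcome = drop_null(list(family = sc$outcome$family,
                   beta0 = sc$outcome$intercept, beta_a = sc$outcome$coef_a,
                   beta_m = sc$outcome$coef_m, beta_i = sc$outcome$coef_i,
                   beta_c = sc$outcome$coef_c, beta_u = sc$outcome$coef_u,
                   sigma = model_sigma(sc$outcome))),
    options = list(n_draws = config$options$n_draws,
                   alpha = config$options$alpha,
                   treat = config$options$treat,
                   control = config$options$control,
                   interaction = config$options$interaction),
    sweep_grid = config$sweep_grid,
    output_prefix = config$output_prefix)
  yaml::write_yaml(drop_null(out), path)
  invisible(path)
}

drop_null <- function(x) x[!vapply(x, is.null, TRUE)]

#' @export
print.umed_config <- function(x, ...) {
  cat(sprintf("Study configuration: n = %d, n_sim = %d, seed = %d\n",
              x$n, x$n_sim, x$master_seed))
  if (!is.null(x$sweep_grid))
    cat("  sweep grid:", paste(x$sweep_grid, collapse = ", "), "\n")
  print(x$scenario)
  invisible(x)
}
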