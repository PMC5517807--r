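#' Run one paired with/without-U iteration
#'
#' Simulates one dataset from the scenario on the iteration's own seed
#' substream, then runs [estimate_mediation()] twice on that same dataset:
#' once omitting the unmeasured confounders U from the fitted models, once
#' including them. Non-convergence of either arm is recorded in the flags and
#' never raised as an error.
#'
#' Each randomised stage -- data generation, the without-U draws and the
#' with-U draws -- gets its own substream derived from
#' `(master_seed, iteration)` (see [substream_seed()]), so the record is
#' independent of which other iterations run in the same process.
#'
#' @param scenario a [mediation_scenario()] with at least one unmeasured
#'   confounder (with none, the two arms coincide).
#' @param n sample size per simulated dataset.
#' @param options a [mediation_options()].
#' @param master_seed master seed for the study.
#' @param iteration iteration index (1-based).
#' @return an object of class `paired_record`: list with `iteration`,
#'   `master_seed`, `without_u` and `with_u` (`mediation_result`s computed on
#'   the same data) and `correlations` (the dataset's
#'   [correlation_matrix()]).
#' @export
run_iteration <- function(scenario, n, options = mediation_options(),
                          master_seed = 1L, iteration = 1L) {
  stopifnot(inherits(scenario, "umed_scenario"))
  has_u <- length(scenario$unmeasured) > 0
  set.seed(substream_seed(master_seed, iteration, 0L))
  d <- simulate_dataset(scenario, n)
  cm <- correlation_matrix(d)
  set.seed(substream_seed(master_seed, iteration, 1L))
  without_u <- estimate_mediation(d, scenario, include_u = FALSE,
                                  options = options)
  set.seed(substream_seed(master_seed, iteration, 2L))
  with_u <- if (has_u)
    estimate_mediation(d, scenario, include_u = TRUE, options = options)
  else without_u
  structure(list(iteration = as.integer(iteration),
                 master_seed = as.integer(master_seed),
                 without_u = without_u, with_u = with_u,
                 correlations = cm),
            class = "paired_record")
}

record_converged <- function(r)
  isTRUE(r$without_u$converged) && isTRUE(r$with_u$converged)

conclusions_match <- function(sig_a, sig_b, est_a, est_b) {
  # same significance status; when both significant, also the same sign
  (!sig_a & !sig_b) | (sig_a & sig_b & sign(est_a) == sign(est_b))
}

#' Aggregate paired records into the study summary
#'
#' Computes, over the converged iterations only: the proportion of
#' iterations in which the mediated (ACME) and direct (ADE) effects are
#' significant in each arm; the proportion in which the two arms reach
#' matching conclusions (same significance status, and same sign when both
#' significant); the average estimates per arm; the average absolute
#' difference between the arms' estimates; and the elementwise average of the
#' per-iteration correlation matrices.
#'
#' @param records list of `paired_record` objects from [run_iteration()].
#' @return an object of class `umed_summary`.
#' @export
summarize_records <- function(records) {
  if (!length(records)) stop("no records to summarize", call. = FALSE)
  stopifnot(all(vapply(records, inherits, TRUE, "paired_record")))
  conv <- vapply(records, record_converged, TRUE)
  if (!any(conv))
    stop("no converged iterations: inspect the per-iteration convergence ",
         "flags (separation or rank deficiency in the fitted models)",
         call. = FALSE)
  rc <- records[conv]
  g <- function(arm, field, mode = numeric(1))
    vapply(rc, function(r) r[[arm]][[field]], mode)
  acme_wo <- g("without_u", "acme"); acme_wi <- g("with_u", "acme")
  ade_wo <- g("without_u", "ade"); ade_wi <- g("with_u", "ade")
  sig_acme_wo <- g("without_u", "acme_sig", logical(1))
  sig_acme_wi <- g("with_u", "acme_sig", logical(1))
  sig_ade_wo <- g("without_u", "ade_sig", logical(1))
  sig_ade_wi <- g("with_u", "ade_sig", logical(1))
  avg_cor <- Reduce(`+`, lapply(rc, `[[`, "correlations")) / length(rc)
  structure(list(
    n_sim = length(records),
    n_converged = length(rc),
    prop_med_sig_without_u = mean(sig_acme_wo),
    prop_med_sig_with_u = mean(sig_acme_wi),
    prop_dir_sig_without_u = mean(sig_ade_wo),
    prop_dir_sig_with_u = mean(sig_ade_wi),
    prop_match_mediated = mean(conclusions_match(sig_acme_wo, sig_acme_wi,
                                                 acme_wo, acme_wi)),
    prop_match_direct = mean(conclusions_match(sig_ade_wo, sig_ade_wi,
                                               ade_wo, ade_wi)),
    avg_acme_without_u = mean(acme_wo),
    avg_acme_with_u = mean(acme_wi),
    avg_ade_without_u = mean(ade_wo),
    avg_ade_with_u = mean(ade_wi),
    avg_abs_diff_acme = mean(abs(acme_wi - acme_wo)),
    avg_abs_diff_ade = mean(abs(ade_wi - ade_wo)),
    avg_correlations = avg_cor), class = "umed_summary")
}

#' @export
print.umed_summary <- function(x, digits = 4, ...) {
  cat("Unmeasured-confounding sensitivity summary\n")
  cat(sprintf("  iterations: %d (%d converged)\n", x$n_sim, x$n_converged))
  f <- function(v) formatC(v, digits = digits, format = "f")
  cat("                                 without U    with U\n")
  cat(sprintf("  prop. mediated significant    %9s %9s\n",
              f(x$prop_med_sig_without_u), f(x$prop_med_sig_with_u)))
  cat(sprintf("  prop. direct significant      %9s %9s\n",
              f(x$prop_dir_sig_without_u), f(x$prop_dir_sig_with_u)))
  cat(sprintf("  average ACME                  %9s %9s\n",
              f(x$avg_acme_without_u), f(x$avg_acme_with_u)))
  cat(sprintf("  average ADE                   %9s %9s\n",
              f(x$avg_ade_without_u), f(x$avg_ade_with_u)))
  cat(sprintf("  prop. conclusions match: mediated %s, direct %s\n",
              f(x$prop_match_mediated), f(x$prop_match_direct)))
  cat(sprintf("  avg |with U - without U|: ACME %s, ADE %s\n",
              f(x$avg_abs_diff_acme), f(x$avg_abs_diff_ade)))
  cat("  average correlations:\n")
  print(round(x$avg_correlations, 3))
  invisible(x)
}

#' Run a full paired simulation study
#'
#' The core sensitivity loop: for each iteration, simulate a dataset and
#' estimate the mediation model with and without the unmeasured confounders,
#' then aggregate with [summarize_records()]. Iterations are seeded by
#' `(master_seed, iteration)` substreams, so a study can be split across
#' machines by passing disjoint `iterations` subsets and merged afterwards
#' with [merge_records()] -- the merged summary is identical to the
#' monolithic run.
#'
#' @param scenario a [mediation_scenario()].
#' @param n sample size per simulated dataset.
#' @param n_sim number of simulation iterations.
#' @param master_seed master seed for the study.
#' @param options a [mediation_options()].
#' @param iterations which iteration indices to run (default `1:n_sim`);
#'   use disjoint subsets for partitioned runs.
#' @param verbose echo convergence failures as they occur.
#' @return an object of class `umed_study`: list with `summary`
#'   (`umed_summary`), `records` (list of `paired_record`), `n`, `n_sim`,
#'   `master_seed`.
#' @examples
#' sc <- mediation_scenario(
#'   unmeasured = list(normal_confounder(0, 1)),
#'   exposure   = exposure_model(gamma_u = 1),
#'   mediator   = mediator_model(alpha_a = 0.5, alpha_u = 1),
#'   outcome    = outcome_model(beta_a = 0.3, beta_m = 0.8, beta_u = 1))
#' st <- run_umediation(sc, n = 200, n_sim = 5, master_seed = 1,
#'                      options = mediation_options(n_draws = 200))
#' st$summary
#' @export
run_umediation <- function(scenario, n, n_sim, master_seed = 1L,
                           options = mediation_options(),
                           iterations = NULL, verbose = FALSE) {
  stopifnot(is.numeric(n_sim), n_sim >= 1)
  if (is.null(iterations)) iterations <- seq_len(n_sim)
  records <- vector("list", length(iterations))
  for (k in seq_along(iterations)) {
    records[[k]] <- run_iteration(scenario, n, options, master_seed,
                                  iterations[k])
    if (verbose && !record_converged(records[[k]]))
      message("iteration ", iterations[k], ": model fit did not converge")
  }
  structure(list(summary = summarize_records(records), records = records,
                 n = as.integer(n), n_sim = as.integer(n_sim),
                 master_seed = as.integer(master_seed)),
            class = "umed_study")
}

#' @export
print.umed_study <- function(x, ...) {
  cat(sprintf("Paired mediation study: n = %d per dataset, seed %d\n",
              x$n, x$master_seed))
  print(x$summary)
  invisible(x)
}

#' Merge partitioned study records
#'
#' Concatenates per-iteration records produced on separate machines (or in
#' separate calls with disjoint `iterations`) and summarises the union.
#' Records are ordered by `(master_seed, iteration)` before aggregation, so
#' the result is identical to the monolithic run covering the same
#' iterations. Duplicate `(master_seed, iteration)` keys are rejected as a
#' double-counting guard.
#'
#' @param record_sets list of record lists; `umed_study` objects are also
#'   accepted and contribute their `records`.
#' @return a `umed_summary` over the union of all records.
#' @export
merge_records <- function(record_sets) {
  if (!length(record_sets)) stop("no record sets to merge", call. = FALSE)
  flat <- list()
  for (s in record_sets) {
    if (inherits(s, "umed_study")) s <- s$records
    if (inherits(s, "paired_record")) s <- list(s)
    flat <- c(flat, s)
  }
  if (!length(flat)) stop("no records to merge", call. = FALSE)
  keys <- vapply(flat, function(r) paste(r$master_seed, r$iteration), "")
  if (anyDuplicated(keys))
    stop("duplicate iteration keys in merge (seed, iteration): ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "),
         call. = FALSE)
  ms <- vapply(flat, `[[`, 0L, "master_seed")
  it <- vapply(flat, `[[`, 0L, "iteration")
  flat <- flat[order(ms, it)]
  summarize_records(flat)
}

#' Sweep the unmeasured-confounder effect size
#'
#' For each effect size `e` on the grid, sets every unmeasured-confounder
#' path coefficient in the three structural models to `e`
#' (`gamma_U = alpha_U = beta_U = e`, applied to all U simultaneously -- the
#' contrast of interest when asking how strong confounding must be before
#' conclusions change) and runs [run_umediation()] with a grid-point-specific
#' seed derived from `(master_seed, grid index)`.
#'
#' @param scenario base [mediation_scenario()] with at least one unmeasured
#'   confounder.
#' @param grid strictly increasing numeric vector of effect sizes.
#' @param n,n_sim,master_seed,options as in [run_umediation()].
#' @return an object of class `umed_sweep`: list with `grid`, `summaries`
#'   (one `umed_summary` per grid point), `studies` (the full `umed_study`
#'   objects) and `swept` (a description of the swept parameters).
#' @export
sweep_confounder_effect <- function(scenario, grid, n, n_sim,
                                    master_seed = 1L,
                                    options = mediation_options()) {
  stopifnot(inherits(scenario, "umed_scenario"), is.numeric(grid),
            length(grid) >= 1)
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  ku <- length(scenario$unmeasured)
  if (ku == 0)
    stop("scenario has no unmeasured confounders to sweep", call. = FALSE)
  studies <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    e <- grid[gi]
    sc <- scenario
    sc$exposure$coef_u <- rep(e, ku)
    sc$mediator$coef_u <- rep(e, ku)
    sc$outcome$coef_u <- rep(e, ku)
    studies[[gi]] <- run_umediation(
      sc, n = n, n_sim = n_sim,
      master_seed = substream_seed(master_seed, gi, 9L),
      options = options)
  }
  structure(list(grid = as.numeric(grid),
                 summaries = lapply(studies, `[[`, "summary"),
                 studies = studies,
                 swept = sprintf("gamma_U = alpha_U = beta_U = e for all %d unmeasured confounder(s)", ku)),
            class = "umed_sweep")
}

#' @export
print.umed_sweep <- function(x, ...) {
  cat("Confounder effect-size sweep (", x$swept, ")\n", sep = "")
  df <- data.frame(
    effect = x$grid,
    prop_match_mediated = vapply(x$summaries, `[[`, 0, "prop_match_mediated"),
    prop_match_direct = vapply(x$summaries, `[[`, 0, "prop_match_direct"),
    avg_abs_diff_acme = vapply(x$summaries, `[[`, 0, "avg_abs_diff_acme"),
    avg_abs_diff_ade = vapply(x$summaries, `[[`, 0, "avg_abs_diff_ade"))
  print(df, row.names = FALSE)
  invisible(x)
}
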