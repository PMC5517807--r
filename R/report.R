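#' Flatten paired records to a data frame
#'
#' One row per iteration with the seed key, both arms' estimates, interval
#' bounds, significance and convergence flags, and the upper triangle of the
#' dataset's correlation matrix (columns `cor_<v1>_<v2>`). This flat form is
#' the merge interchange format: every summary number is recomputable from
#' it.
#'
#' @param records list of `paired_record` objects (or a `umed_study`).
#' @return a data frame, ordered by `(master_seed, iteration)`.
#' @export
records_frame <- function(records) {
  if (inherits(records, "umed_study")) records <- records$records
  stopifnot(length(records) >= 1)
  arm_cols <- function(r, arm, prefix) {
    a <- r[[arm]]
    setNames(
      list(a$acme, a$acme_lower, a$acme_upper, isTRUE(a$acme_sig),
           a$ade, a$ade_lower, a$ade_upper, isTRUE(a$ade_sig),
           a$total, isTRUE(a$converged)),
      paste0(prefix, c("acme", "acme_lower", "acme_upper", "acme_sig",
                       "ade", "ade_lower", "ade_upper", "ade_sig",
                       "total", "converged")))
  }
  rows <- lapply(records, function(r) {
    cm <- r$correlations
    vars <- colnames(cm)
    ut <- which(upper.tri(cm), arr.ind = TRUE)
    cors <- setNames(cm[upper.tri(cm)],
                     paste0("cor_", vars[ut[, 1]], "_", vars[ut[, 2]]))
    as.data.frame(c(list(master_seed = r$master_seed,
                         iteration = r$iteration),
                    arm_cols(r, "without_u", "wo_"),
                    arm_cols(r, "with_u", "wu_"),
                    as.list(cors)))
  })
  df <- do.call(rbind, rows)
  df[order(df$master_seed, df$iteration), , drop = FALSE]
}

# full-precision CSV so a write/read round trip is numerically exact
write_precise_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- vapply(out[[j]], function(v)
        if (is.na(v)) "NA" else sprintf("%.17g", v), "")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read per-iteration record files
#'
#' `write_records()` stores the flat per-iteration table as CSV at full
#' precision; `read_records()` reconstructs the `paired_record` list
#' (interval bounds, flags and correlation matrices included), so that
#' partitioned runs can be merged from files via [merge_records()] with
#' results identical to the in-memory merge.
#'
#' @param records list of `paired_record` objects or a `umed_study`.
#' @param path CSV file path.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   returns a list of `paired_record` objects.
#' @export
write_records <- function(records, path) {
  write_precise_csv(records_frame(records), path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cor_cols <- grep("^cor_", names(df), value = TRUE)
  vars <- unique(unlist(strsplit(sub("^cor_", "", cor_cols), "_")))
  k <- length(vars)
  arm_from_row <- function(row, prefix) {
    g <- function(f) row[[paste0(prefix, f)]]
    structure(list(
      acme = g("acme"), acme_lower = g("acme_lower"),
      acme_upper = g("acme_upper"), acme_sig = as.logical(g("acme_sig")),
      ade = g("ade"), ade_lower = g("ade_lower"), ade_upper = g("ade_upper"),
      ade_sig = as.logical(g("ade_sig")),
      total = g("total"), total_lower = NA_real_, total_upper = NA_real_,
      acme_mc_se = NA_real_, ade_mc_se = NA_real_, n_draws = NA_integer_,
      converged = as.logical(g("converged"))), class = "mediation_result")
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    cm <- diag(1, k); dimnames(cm) <- list(vars, vars)
    for (cc in cor_cols) {
      pair <- match_cor_pair(sub("^cor_", "", cc), vars)
      cm[pair[1], pair[2]] <- cm[pair[2], pair[1]] <- row[[cc]]
    }
    structure(list(iteration = as.integer(row$iteration),
                   master_seed = as.integer(row$master_seed),
                   without_u = arm_from_row(row, "wo_"),
                   with_u = arm_from_row(row, "wu_"),
                   correlations = cm),
              class = "paired_record")
  })
}

# split "A_M" back into its two variable names (labels contain no underscore)
match_cor_pair <- function(s, vars) {
  parts <- strsplit(s, "_")[[1]]
  stopifnot(length(parts) == 2, all(parts %in% vars))
  parts
}

summary_fields <- function(s) {
  list(n_sim = s$n_sim, n_converged = s$n_converged,
       prop_med_sig_without_u = s$prop_med_sig_without_u,
       prop_med_sig_with_u = s$prop_med_sig_with_u,
       prop_dir_sig_without_u = s$prop_dir_sig_without_u,
       prop_dir_sig_with_u = s$prop_dir_sig_with_u,
       prop_match_mediated = s$prop_match_mediated,
       prop_match_direct = s$prop_match_direct,
       avg_acme_without_u = s$avg_acme_without_u,
       avg_acme_with_u = s$avg_acme_with_u,
       avg_ade_without_u = s$avg_ade_without_u,
       avg_ade_with_u = s$avg_ade_with_u,
       avg_abs_diff_acme = s$avg_abs_diff_acme,
       avg_abs_diff_ade = s$avg_abs_diff_ade)
}

summary_json <- function(s) {
  out <- summary_fields(s)
  cm <- s$avg_correlations
  out$avg_correlations <- list(variables = colnames(cm),
                               matrix = unname(apply(cm, 1, as.list,
                                                     simplify = FALSE)))
  out
}

#' Write a summary as text and JSON
#'
#' Writes `<prefix>_summary.txt` (human-readable table of every summary
#' field) and `<prefix>_summary.json` (machine-readable, full precision).
#' Field order is fixed, so re-running on the same object reproduces
#' byte-identical files.
#'
#' @param summary a `umed_summary` object.
#' @param prefix output path prefix (directories are created as needed).
#' @return character vector of the files written, invisibly.
#' @export
write_summary <- function(summary, prefix) {
  stopifnot(inherits(summary, "umed_summary"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  files <- paste0(prefix, c("_summary.txt", "_summary.json"))
  writeLines(capture_print(summary), files[1])
  jsonlite::write_json(summary_json(summary), files[2],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}

#' Write study reports
#'
#' For a `umed_study`: writes `<prefix>_summary.txt` (human-readable table),
#' `<prefix>_summary.json` (machine-readable) and `<prefix>_records.csv`
#' (per-iteration audit trail, see [write_records()]). For a `umed_sweep`:
#' writes `<prefix>_sweep.csv` (one summary row per grid point, keyed by
#' effect size), `<prefix>_sweep.json` and `<prefix>_records.csv` with an
#' extra leading `effect` column. Field order is fixed, so re-running on the
#' same object reproduces byte-identical files.
#'
#' @param x a `umed_study` or `umed_sweep` object.
#' @param prefix output path prefix (directories are created as needed).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(x, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "umed_study")) {
    files <- c(write_summary(x$summary, prefix),
               paste0(prefix, "_records.csv"))
    write_records(x$records, files[3])
  } else if (inherits(x, "umed_sweep")) {
    files <- paste0(prefix, c("_sweep.csv", "_sweep.json", "_records.csv"))
    rows <- lapply(seq_along(x$grid), function(gi)
      as.data.frame(c(list(effect = x$grid[gi]),
                      summary_fields(x$summaries[[gi]]))))
    write_precise_csv(do.call(rbind, rows), files[1])
    jsonlite::write_json(
      list(swept = x$swept, grid = x$grid,
           summaries = lapply(x$summaries, summary_json)),
      files[2], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    recs <- do.call(rbind, lapply(seq_along(x$grid), function(gi)
      cbind(effect = x$grid[gi], records_frame(x$studies[[gi]]))))
    write_precise_csv(recs, files[3])
  } else stop("write_report() expects a umed_study or umed_sweep object",
              call. = FALSE)
  invisible(files)
}

capture_print <- function(x) utils::capture.output(print(x))

#' Read a sweep report back from JSON
#'
#' Reconstructs the grid and summary fields of a sweep from the
#' `<prefix>_sweep.json` file written by [write_report()], sufficient for
#' [plot_sweep()].
#'
#' @param path path to a `*_sweep.json` file.
#' @return a `umed_sweep`-like object (without the raw studies).
#' @export
read_sweep_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  summaries <- lapply(j$summaries, function(s) {
    s$avg_correlations <- NULL
    s
  })
  structure(list(grid = as.numeric(unlist(j$grid)), summaries = summaries,
                 studies = NULL, swept = j$swept),
            class = "umed_sweep")
}
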