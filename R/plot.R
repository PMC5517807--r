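#' Plot conclusion-match proportions along a confounder effect-size sweep
#'
#' Line plot of the proportion of simulations in which the with-U and
#' without-U analyses reach the same conclusion, for the mediated and the
#' direct effect, as a function of the unmeasured-confounder effect size.
#' Several sweeps (e.g. one vs. two unmeasured confounders) are drawn as
#' side-by-side panels.
#'
#' @param sweeps a `umed_sweep` object (from [sweep_confounder_effect()] or
#'   [read_sweep_json()]), or a named list of them (names become panel
#'   titles).
#' @param path optional output file; written via [ggplot2::ggsave()], format
#'   chosen by the extension (`.png`, `.svg`, `.pdf`). When `NULL` the plot
#'   object is only returned.
#' @param width,height device size in inches when `path` is given.
#' @return the `ggplot` object, invisibly.
#' @export
plot_sweep <- function(sweeps, path = NULL, width = 7, height = 4.5) {
  if (inherits(sweeps, "umed_sweep")) sweeps <- list(sweep = sweeps)
  stopifnot(is.list(sweeps), length(sweeps) >= 1,
            all(vapply(sweeps, inherits, TRUE, "umed_sweep")))
  if (is.null(names(sweeps)) || any(!nzchar(names(sweeps))))
    names(sweeps) <- paste("sweep", seq_along(sweeps))
  if (any(vapply(sweeps, function(s) length(s$grid), 0L) < 2))
    stop("a sweep needs at least 2 grid points to plot; ",
         "use write_report() for a single point", call. = FALSE)
  df <- do.call(rbind, lapply(names(sweeps), function(nm) {
    s <- sweeps[[nm]]
    data.frame(
      panel = nm,
      effect = rep(s$grid, 2),
      proportion = c(
        vapply(s$summaries, function(x) as.numeric(x$prop_match_mediated), 0),
        vapply(s$summaries, function(x) as.numeric(x$prop_match_direct), 0)),
      series = rep(c("mediated effect", "direct effect"),
                   each = length(s$grid)))
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = effect, y = proportion,
                                        colour = series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "unmeasured confounder effect size (gamma_U = alpha_U = beta_U)",
                  y = "proportion of simulations with matching conclusions",
                  colour = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "bottom")
  if (length(sweeps) > 1)
    p <- p + ggplot2::facet_wrap(~panel)
  if (!is.null(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    ggplot2::ggsave(path, p, width = width, height = height)
  }
  invisible(p)
}

utils::globalVariables(c("effect", "proportion", "series"))
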