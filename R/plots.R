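#' Manhattan-style export and plot of window variances
#'
#' `export_manhattan()` writes a TSV with a cumulative genome coordinate
#' (window start plus the summed lengths of the preceding chromosomes, in
#' report order), ready for plotting; `plot_manhattan()` draws the profile
#' of the per-window percentage of additive genetic variance.
#'
#' @param report A `window_report` from [window_variances()].
#' @param path Output TSV path.
#' @param threshold_pct Optional horizontal reference line for
#'   `plot_manhattan()`, default 1 (the selection threshold); `NULL`
#'   suppresses it.
#' @return `export_manhattan()` returns the written tibble invisibly;
#'   `plot_manhattan()` a ggplot object.
#' @export
export_manhattan <- function(report, path) {
  out <- manhattan_coords(report)
  readr::write_tsv(out, path)
  invisible(out)
}

manhattan_coords <- function(report) {
  rep_tb <- as_tibble(report)
  chroms <- unique(rep_tb$chrom)
  chrom_len <- vapply(chroms, function(cc)
    max(rep_tb$end_bp[rep_tb$chrom == cc]), numeric(1))
  offsets <- setNames(c(0, cumsum(as.numeric(chrom_len)))[seq_along(chroms)],
                      chroms)
  dplyr::mutate(rep_tb,
                cum_bp = .data$start_bp + unname(offsets[as.character(.data$chrom)]),
                .after = "end_bp")
}

#' @rdname export_manhattan
#' @export
plot_manhattan <- function(report, threshold_pct = 1) {
  dat <- manhattan_coords(report)
  dat$chrom <- factor(dat$chrom, levels = unique(dat$chrom))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$cum_bp,
                                         y = .data$pct_variance,
                                         colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = rep(c("grey25", "steelblue"), length.out = nlevels(dat$chrom))) +
    ggplot2::labs(x = "Genome position (cumulative bp)",
                  y = "Additive genetic variance explained (%)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold_pct))
    p <- p + ggplot2::geom_hline(yintercept = threshold_pct,
                                 linetype = "dashed", colour = "firebrick")
  p
}

#' @export
autoplot.window_report <- function(object, ...) plot_manhattan(object, ...)

#' Trace plot of the variance-component chains
#'
#' @param object An `ssgblup_fit`.
#' @param ... Unused.
#' @return A ggplot object with one facet per monitored scalar.
#' @export
autoplot.ssgblup_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$chains, -"iteration",
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Iteration", y = NULL) +
    ggplot2::theme_minimal()
}
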