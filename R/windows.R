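#' Variance explained by windows of adjacent SNPs
#'
#' Partitions the additive genetic variance into non-overlapping blocks of
#' `window_size` map-consecutive SNPs within each chromosome (a trailing
#' remainder forms a short window, flagged by its `n_snps`). The window
#' genetic value is `a_w = sum_j Z_j u_j` over the member SNPs, evaluated
#' across the genotyped animals, and the reported percentage is
#' `Var(a_w) / sigma2_a * 100`.
#'
#' @param u_hat Per-SNP effects, in map order.
#' @param Z Centred gene content of the genotyped animals, in map order.
#' @param sigma2_a Total additive genetic variance (positive), typically
#'   the posterior mean of the initial fit.
#' @param map SNP map tibble (`snp_id`, `chrom`, `pos_bp`).
#' @param window_size Number of adjacent SNPs per window, default 10.
#' @return A `window_report` tibble: `window`, `chrom`, `start_snp`,
#'   `end_snp`, `start_bp`, `end_bp`, `n_snps`, `pct_variance`.
#' @export
window_variances <- function(u_hat, Z, sigma2_a, map, window_size = 10L) {
  if (window_size < 1L) abort("`window_size` must be at least 1")
  if (sigma2_a <= 0) abort("`sigma2_a` must be positive")
  m <- nrow(map)
  if (length(u_hat) != m || ncol(Z) != m)
    abort("`u_hat`, `Z` and `map` disagree on the number of SNPs")
  chroms <- unique(map$chrom)
  rows <- list()
  ord <- 0L
  for (cc in chroms) {
    idx <- which(map$chrom == cc)
    nwin <- ceiling(length(idx) / window_size)
    for (wk in seq_len(nwin)) {
      member <- idx[seq.int((wk - 1L) * window_size + 1L,
                            min(wk * window_size, length(idx)))]
      av <- as.numeric(Z[, member, drop = FALSE] %*% u_hat[member])
      ord <- ord + 1L
      rows[[ord]] <- tibble(
        window = ord, chrom = cc,
        start_snp = map$snp_id[member[1L]],
        end_snp = map$snp_id[member[length(member)]],
        start_bp = map$pos_bp[member[1L]],
        end_bp = map$pos_bp[member[length(member)]],
        n_snps = length(member),
        pct_variance = 100 * var(av) / sigma2_a
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("window_report", class(out))
  out
}

#' Select candidate QTL windows
#'
#' Windows explaining at least `threshold_pct` of the additive genetic
#' variance, sorted by explained variance (descending), ties broken by
#' chromosome and position.
#'
#' @param report A `window_report` from [window_variances()].
#' @param threshold_pct Selection threshold in percent, default 1.
#' @return The selected subset, sorted; empty if nothing reaches the
#'   threshold.
#' @export
select_regions <- function(report, threshold_pct = 1) {
  out <- dplyr::arrange(
    dplyr::filter(report, .data$pct_variance >= threshold_pct),
    dplyr::desc(.data$pct_variance), .data$chrom, .data$start_bp)
  class(out) <- unique(c("window_report", class(out)))
  out
}
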