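#' End-to-end weighted single-step GWAS
#'
#' Convenience wrapper chaining the whole pipeline on already-loaded
#' tables: genotype/phenotype quality control, mean imputation,
#' relationship matrices (sparse A inverse, A22, tuned + blended G,
#' H inverse), Gibbs estimation of the variance components, the iterative
#' SNP-weighting loop at the posterior-mean variances, and the window
#' variance decomposition with candidate-region selection.
#'
#' @param ped Pedigree tibble (`animal`, `sire`, `dam`), topologically
#'   ordered.
#' @param geno A [geno_matrix()] of the genotyped animals.
#' @param phen Phenotype tibble (`animal_id`, `trait_value`, `cg`, `age`).
#' @param thresholds A [qc_thresholds()].
#' @param chain Gibbs chain settings, see [gibbs_fit()].
#' @param n_iter Weighting rounds, default 2.
#' @param window_size SNPs per window, default 10.
#' @param threshold_pct Selection threshold in percent, default 1.
#' @param blend_epsilon G blending fraction, default 0.05.
#' @param variance_components Optional list `(sigma2_a, sigma2_e)`; when
#'   supplied the Gibbs stage is skipped and the weighting loop runs at
#'   these values.
#' @return An object of class `wssgwas_result`: QC reports, the fit (or
#'   `NULL` when variances were supplied), per-iteration `solutions`,
#'   the final `windows` report and the `selected` regions.
#' @export
run_ssgwas <- function(ped, geno, phen,
                       thresholds = qc_thresholds(),
                       chain = list(length = 50000L, burn_in = 5000L,
                                    thin = 10L, seed = 1L),
                       n_iter = 2L, window_size = 10L, threshold_pct = 1,
                       blend_epsilon = 0.05,
                       variance_components = NULL) {
  qc_g <- filter_snps(geno, thresholds)
  qc_p <- filter_contemporary_groups(phen, thresholds)
  geno_i <- impute_genotypes(qc_g$geno)

  design <- build_design_matrices(qc_p$phen, ped)
  a_inv <- build_A_inverse(ped)
  gids <- rownames(geno_i$calls)
  a22 <- build_A22(ped, gids)

  fit <- NULL
  if (is.null(variance_components)) {
    g_raw <- build_raw_G(geno_i)
    tuned <- tune_G(g_raw, a22)
    g_final <- blend_G(tuned$g_tuned, a22, blend_epsilon)
    h_inv <- build_H_inverse(a_inv, a22, g_final, gids)
    fit <- gibbs_fit(design$y, design$X, design$Z, h_inv, chain = chain)
    variance_components <- list(sigma2_a = mean(fit$chains$sigma2_a),
                                sigma2_e = mean(fit$chains$sigma2_e))
  }

  solutions <- run_weighted_iterations(
    geno_i, design, a_inv, a22,
    sigma2_a = variance_components$sigma2_a,
    sigma2_e = variance_components$sigma2_e,
    n_iter = n_iter, blend_epsilon = blend_epsilon)
  final <- solutions[[length(solutions)]]
  Z <- centered_gene_content(geno_i)
  windows <- window_variances(final$snp$u_hat, Z,
                              variance_components$sigma2_a,
                              geno_i$map, window_size)
  selected <- select_regions(windows, threshold_pct)

  structure(list(
    qc = list(snp_report = qc_g$report, cg_report = qc_p$report),
    geno = geno_i, design = design, fit = fit,
    variance_components = variance_components,
    solutions = solutions, windows = windows, selected = selected
  ), class = "wssgwas_result")
}

#' @export
print.wssgwas_result <- function(x, ...) {
  cat(sprintf("<wssgwas_result> %d records, %d genotyped animals, %d SNPs\n",
              length(x$design$y), nrow(x$geno$calls), ncol(x$geno$calls)))
  cat(sprintf("  sigma2_a = %.4f, sigma2_e = %.4f (h2 = %.3f)\n",
              x$variance_components$sigma2_a, x$variance_components$sigma2_e,
              x$variance_components$sigma2_a /
                (x$variance_components$sigma2_a + x$variance_components$sigma2_e)))
  cat(sprintf("  %d weighting iteration(s); %d/%d windows at or above threshold\n",
              length(x$solutions), nrow(x$selected), nrow(x$windows)))
  invisible(x)
}
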