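#' Back-solve SNP effects from genomic breeding values
#'
#' `u = D Z' [Z D Z']^-1 a_g`: distributes the GEBVs of the genotyped
#' animals over the markers that generated them, so that `Z u` reproduces
#' the GEBVs (any scalar tuning of the operator cancels algebraically).
#'
#' The operator is inverted on its range (a symmetric-eigenvalue
#' pseudo-inverse), so the solve is the minimum-norm least-squares
#' decomposition of the GEBVs over the markers. With a full-rank operator
#' the plain identity `Z u = a_g` holds to machine precision. When `Z` is
#' centred at the observed allele frequencies its columns sum to zero, so
#' `Z D Z'` carries an exact rank-one null space along the vector of ones:
#' marker effects can never reproduce the genotyped-group mean GEBV (the
#' genetic base), only the deviations from it; the mean of the unexplained
#' remainder is returned in `attr(u, "base")` and `Z u + base` then
#' reproduces `a_g` to machine precision. An identically zero operator
#' raises an error advising a blended operator.
#'
#' @param a_g_hat GEBVs of the genotyped animals, in the row order of `Z`.
#' @param Z Centred gene content (calls - 2p) of the genotyped animals.
#' @param d Per-SNP weights `D` (default 1).
#' @param M Optional custom operator to invert in place of `Z D Z'`
#'   (e.g. a blended G rescaled to the `Z D Z'` scale; the identity is
#'   then approximate to order of the blend).
#' @return Numeric vector of per-SNP effects (trait units per allele),
#'   with attribute `base` (scalar).
#' @export
backsolve_snp_effects <- function(a_g_hat, Z, d = NULL, M = NULL) {
  m <- ncol(Z)
  ng <- nrow(Z)
  if (is.null(d)) d <- rep(1, m)
  if (length(d) != m || any(d < 0))
    abort("`d` must be a non-negative vector, one entry per SNP")
  if (length(a_g_hat) != ng)
    abort("`a_g_hat` length must equal the number of genotyped animals")
  if (is.null(M)) {
    Zw <- sweep(Z, 2L, sqrt(d), `*`)
    M <- tcrossprod(Zw)
  }
  eg <- eigen((M + base::t(M)) / 2, symmetric = TRUE)
  tol <- 1e-10 * max(eg$values, 0)
  keep <- eg$values > tol
  if (!any(keep))
    abort("ZDZ' is identically singular; supply a blended operator via `M`")
  Vk <- eg$vectors[, keep, drop = FALSE]
  t_vec <- Vk %*% (crossprod(Vk, a_g_hat) / eg$values[keep])
  u <- as.numeric(d * crossprod(Z, t_vec))
  attr(u, "base") <- if (all(keep)) 0 else mean(a_g_hat - as.numeric(Z %*% u))
  u
}

#' Per-SNP variance weights
#'
#' `d_i = u_i^2 * 2 p_i (1 - p_i)`: each marker's share of additive
#' variance under Hardy-Weinberg and linkage equilibrium.
#'
#' @param u_hat Per-SNP effect estimates.
#' @param p Allele frequencies, strictly inside (0, 1).
#' @return Numeric weight vector.
#' @export
snp_weights <- function(u_hat, p) {
  if (length(u_hat) != length(p)) abort("`u_hat` and `p` lengths differ")
  if (any(p <= 0 | p >= 1)) abort("allele frequencies must lie strictly in (0, 1)")
  u_hat^2 * 2 * p * (1 - p)
}

#' Normalise SNP weights to conserve total genetic variance
#'
#' Rescales `d` so that `sum_i d_i 2 p_i (1 - p_i)` equals its value under
#' `D = I`, i.e. `sum_i 2 p_i (1 - p_i)` -- the weighting re-distributes,
#' never inflates, the additive variance.
#'
#' @param d Non-negative weights, not all zero.
#' @param p Allele frequencies, strictly inside (0, 1).
#' @return Normalised weight vector.
#' @export
normalize_weights <- function(d, p) {
  if (length(d) != length(p)) abort("`d` and `p` lengths differ")
  if (any(p <= 0 | p >= 1)) abort("allele frequencies must lie strictly in (0, 1)")
  if (any(d < 0)) abort("weights must be non-negative")
  het <- 2 * p * (1 - p)
  denom <- sum(d * het)
  if (denom == 0)
    abort("all SNP weights are zero; degenerate solution")
  d * sum(het) / denom
}

#' Iterative SNP re-weighting (weighted ssGWAS)
#'
#' The core loop: with the current weights `D`, rebuild the genomic
#' relationship matrix (tuned to A22, blended), rebuild `H^-1`, recompute
#' GEBVs by the direct mixed-model solve at the supplied variance
#' components, back-solve SNP effects, square them into weights
#' `u^2 2p(1-p)` and normalise so total genetic variance is conserved.
#' Iterating increases the weights of large-effect SNPs and shrinks the
#' rest. Variance components stay fixed throughout.
#'
#' @param geno Post-QC, imputed [geno_matrix()] of the genotyped animals.
#' @param design Output of [build_design_matrices()].
#' @param a_inv Sparse pedigree inverse over all animals.
#' @param a22 Pedigree relationship matrix of the genotyped animals, in
#'   the row order of `geno`.
#' @param sigma2_a,sigma2_e Variance components (e.g. Gibbs posterior
#'   means), held fixed.
#' @param n_iter Number of weighting rounds, default 2. Round 1 is the
#'   unweighted ssGBLUP back-solve (`D = I`).
#' @param blend_epsilon Blending fraction for G, default 0.05.
#' @return List of per-iteration solutions (class `snp_solution`): each
#'   has `snp` (tibble: `snp_id`, `u_hat`, `d` used, `d_next`, `p`),
#'   `gebv` (all animals), `q` (tuning factor), `iteration`, and
#'   `backsolve_residual` = max |Z u - a_g|.
#' @export
run_weighted_iterations <- function(geno, design, a_inv, a22,
                                    sigma2_a, sigma2_e,
                                    n_iter = 2L, blend_epsilon = 0.05) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (n_iter < 1L) abort("`n_iter` must be at least 1")
  gidx <- match(rownames(geno$calls), design$animal_ids)
  if (anyNA(gidx))
    abort("genotyped animals absent from the pedigree ordering")
  p <- allele_freqs(geno)
  Z <- centered_gene_content(geno, p)
  d <- rep(1, ncol(Z))
  solutions <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    step <- function(expr, what) {
      tryCatch(expr, error = function(e) abort(sprintf(
        "weighting iteration %d failed at %s: %s", it, what,
        conditionMessage(e))))
    }
    g_raw <- step(build_raw_G(geno, weights = d, p = p), "build_raw_G")
    tuned <- step(tune_G(g_raw, a22), "tune_G")
    g_final <- step(blend_G(tuned$g_tuned, a22, blend_epsilon), "blend_G")
    h_inv <- step(build_H_inverse(a_inv, a22, g_final, gidx), "build_H_inverse")
    sol <- step(mme_solve(design$y, design$X, design$Z, h_inv,
                          sigma2_a, sigma2_e), "mme_solve")
    a_g <- sol$a[gidx]
    u <- step(backsolve_snp_effects(a_g, Z, d), "backsolve_snp_effects")
    base_val <- attr(u, "base")
    resid <- max(abs(Z %*% as.numeric(u) + base_val - a_g))
    d_next <- step(normalize_weights(snp_weights(as.numeric(u), p), p),
                   "normalize_weights")
    solutions[[it]] <- structure(list(
      snp = tibble(snp_id = geno$map$snp_id, u_hat = as.numeric(u), d = d,
                   d_next = d_next, p = unname(p)),
      gebv = sol$a, q = tuned$q, iteration = it, base = base_val,
      backsolve_residual = resid
    ), class = "snp_solution")
    d <- d_next
  }
  solutions
}

#' @export
print.snp_solution <- function(x, ...) {
  cat(sprintf("<snp_solution> iteration %d: %d SNPs, max |u| = %.4g, backsolve residual %.2g\n",
              x$iteration, nrow(x$snp), max(abs(x$snp$u_hat)),
              x$backsolve_residual))
  invisible(x)
}
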