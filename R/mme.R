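#' Design matrices for the animal model
#'
#' Builds `y`, the fixed-effect matrix `X` (intercept, contemporary-group
#' indicators with the reference level absorbed, centred slaughter age and
#' centred squared age) and the sparse incidence `Z` mapping records to
#' pedigree animal positions for the model `y = X beta + Z a + e`.
#' Degenerate covariate columns (all ages equal) are dropped with a
#' message; unused contemporary-group levels are dropped.
#'
#' @param phen Phenotype tibble with columns `animal_id`, `trait_value`,
#'   `cg`, `age`.
#' @param ped Pedigree tibble; every phenotyped animal must appear in it.
#' @return List with `y`, `X`, `Z` (sparse records x animals),
#'   `rec_animal` (integer animal position per record) and `animal_ids`.
#' @export
build_design_matrices <- function(phen, ped) {
  need <- c("animal_id", "trait_value", "cg", "age")
  if (!all(need %in% names(phen)))
    abort(paste0("phenotypes need columns ", paste(need, collapse = ", ")))
  rec_animal <- match(as.character(phen$animal_id), as.character(ped$animal))
  if (anyNA(rec_animal)) {
    bad <- unique(phen$animal_id[is.na(rec_animal)])
    abort(paste0("phenotyped animals absent from pedigree: ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  n_rec <- nrow(phen)
  cg <- droplevels(factor(phen$cg))
  X <- stats::model.matrix(~cg, data = data.frame(cg = cg))
  colnames(X)[1L] <- "(Intercept)"
  age_c <- phen$age - mean(phen$age)
  age2_c <- age_c^2 - mean(age_c^2)
  cov_block <- cbind(age = age_c, age2 = age2_c)
  keep <- apply(cov_block, 2L, function(v) var(v) > 0)
  if (!all(keep))
    inform(paste0("dropping degenerate age covariate(s): ",
                  paste(colnames(cov_block)[!keep], collapse = ", ")))
  X <- cbind(X, cov_block[, keep, drop = FALSE])
  if (qr(X)$rank < ncol(X))
    abort("fixed-effect matrix X is rank deficient")
  Z <- Matrix::sparseMatrix(i = seq_len(n_rec), j = rec_animal, x = 1,
                            dims = c(n_rec, nrow(ped)))
  list(y = phen$trait_value, X = X, Z = Z,
       rec_animal = rec_animal, animal_ids = as.character(ped$animal))
}

#' Solve the mixed-model equations directly
#'
#' Henderson's equations with the relationship operator `H^-1`:
#' `[X'X, X'Z; Z'X, Z'Z + lambda H^-1] [beta; a] = [X'y; Z'y]` with
#' `lambda = sigma2_e / sigma2_a`. Serves as the exact inner engine of the
#' SNP-weighting loop and as an oracle for the Gibbs sampler.
#'
#' @param y,X,Z Response, fixed-effect matrix and sparse incidence, as
#'   returned by [build_design_matrices()].
#' @param h_inv An [build_H_inverse()] object, or any symmetric matrix over
#'   the pedigree animals (e.g. a sparse A inverse for pedigree-only BLUP).
#' @param sigma2_a,sigma2_e Additive and residual variances (positive).
#' @return List with `beta` (named), `a` (named breeding values for all
#'   pedigree animals), `lambda` and the linear-system `residual`.
#' @export
mme_solve <- function(y, X, Z, h_inv, sigma2_a, sigma2_e) {
  if (sigma2_a <= 0 || sigma2_e <= 0)
    abort("variances must be positive")
  lambda <- sigma2_e / sigma2_a
  Hd <- if (inherits(h_inv, "h_inverse")) as.matrix(h_inv) else as.matrix(h_inv)
  n <- nrow(Hd)
  if (ncol(Z) != n) abort("Z and H^-1 dimensions disagree")
  XtX <- crossprod(X)
  XtZ <- as.matrix(crossprod(X, Z))
  ZtZ <- as.matrix(crossprod(Z))
  C <- rbind(cbind(XtX, XtZ),
             cbind(t(XtZ), ZtZ + lambda * Hd))
  rhs <- c(as.numeric(crossprod(X, y)), as.numeric(crossprod(Z, y)))
  sol <- tryCatch(solve(C, rhs),
                  error = function(e) abort(paste0(
                    "mixed-model equations are singular: ", conditionMessage(e))))
  resid <- max(abs(C %*% sol - rhs))
  if (resid > 1e-6 * max(1, max(abs(rhs))))
    warn(sprintf("large linear-system residual: %.3g", resid))
  p <- ncol(X)
  ids <- if (inherits(h_inv, "h_inverse")) h_inv$ids else rownames(Hd)
  list(beta = setNames(sol[seq_len(p)], colnames(X)),
       a = setNames(sol[-seq_len(p)], ids),
       lambda = lambda, residual = resid)
}

#' Fit the animal model by Gibbs sampling
#'
#' Single-site Gibbs sampler for `y = X beta + Z a + e` with
#' `a ~ N(0, sigma2_a H)`: flat priors on the fixed effects, scaled
#' inverse chi-square priors on both variance components (the univariate
#' form of the inverted Wishart), normal full conditionals for every
#' location effect (fixed effects first, then animals in pedigree order)
#' and scaled inverse chi-square full conditionals for the variances via
#' the quadratic forms `a' H^-1 a` and `e'e`. The compiled core exploits
#' the sparse-plus-genotyped-block structure of `H^-1`.
#'
#' @inheritParams mme_solve
#' @param chain List: `length` (total iterations), `burn_in`, `thin`,
#'   `seed`. Default 50,000 / 5,000 / 10 -- a desk-scale chain; scale up
#'   for production runs.
#' @param priors Optional list with `nu_a`, `S_a`, `nu_e`, `S_e`. Default:
#'   degrees of freedom 4 and scales set from an ANOVA-style split of the
#'   fixed-effect-adjusted phenotypic variance (half additive, half
#'   residual), i.e. weakly informative.
#' @param fix_variances If `TRUE` the variances stay at their starting
#'   values and only location effects are sampled (used to validate the
#'   sampler against the direct solver).
#' @param start Optional list with starting `sigma2_a`, `sigma2_e`.
#' @return An object of class `ssgblup_fit`: `chains` tibble
#'   (`iteration`, `sigma2_a`, `sigma2_e`, `h2`), posterior-mean `beta`
#'   and `ebv` tibbles, and metadata. Deterministic given `chain$seed`.
#' @export
gibbs_fit <- function(y, X, Z, h_inv,
                      chain = list(length = 50000L, burn_in = 5000L,
                                   thin = 10L, seed = 1L),
                      priors = NULL, fix_variances = FALSE, start = NULL) {
  chain <- utils::modifyList(list(length = 50000L, burn_in = 5000L,
                                  thin = 10L, seed = 1L), as.list(chain))
  if (chain$burn_in >= chain$length)
    abort("burn_in must be smaller than the chain length")
  if (!inherits(h_inv, "h_inverse")) {
    # wrap a plain (sparse or dense) matrix as a correction-free operator
    M <- methods::as(methods::as(Matrix::Matrix(h_inv, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    h_inv <- structure(list(a_inv = M, correction = matrix(0, 0, 0),
                            index = integer(0), n = nrow(M),
                            ids = rownames(M)),
                       class = "h_inverse")
  }
  vr <- var(stats::lm.fit(X, y)$residuals)
  if (is.null(priors))
    priors <- list(nu_a = 4, S_a = vr / 4, nu_e = 4, S_e = vr / 4)
  if (is.null(start))
    start <- list(sigma2_a = vr / 2, sigma2_e = vr / 2)

  rec_animal <- apply_incidence_index(Z)
  A <- methods::as(methods::as(h_inv$a_inv, "generalMatrix"), "CsparseMatrix")
  res <- withr::with_seed(chain$seed,
    .gibbs_ssgblup(as.numeric(y), as.matrix(X), rec_animal,
                   A@p, A@i, A@x,
                   if (length(h_inv$index)) h_inv$correction else matrix(0, 0, 0),
                   h_inv$index, h_inv$n,
                   as.integer(chain$length), as.integer(chain$burn_in),
                   as.integer(chain$thin),
                   priors$nu_a, priors$S_a, priors$nu_e, priors$S_e,
                   start$sigma2_a, start$sigma2_e, isTRUE(fix_variances)))
  chains <- tibble(
    iteration = as.integer(res$samples[, 1L]),
    sigma2_a = res$samples[, 2L],
    sigma2_e = res$samples[, 3L]
  )
  chains$h2 <- chains$sigma2_a / (chains$sigma2_a + chains$sigma2_e)
  ids <- h_inv$ids %||% as.character(seq_len(h_inv$n))
  structure(list(
    chains = chains,
    beta = tibble(term = colnames(X), estimate = res$beta_mean),
    ebv = tibble(animal_id = ids, gebv = res$a_mean),
    meta = list(chain = chain, priors = priors, fix_variances = fix_variances,
                n_records = length(y), n_animals = h_inv$n,
                n_genotyped = length(h_inv$index), n_samples = res$n_kept)
  ), class = "ssgblup_fit")
}

# one-entry-per-row 0/1 incidence -> 1-based animal index per record
apply_incidence_index <- function(Z) {
  s <- Matrix::summary(methods::as(Z, "TsparseMatrix"))
  if (nrow(s) != nrow(Z) || any(s$x != 1) || anyDuplicated(s$i))
    abort("Z must be a 0/1 incidence with exactly one entry per record")
  as.integer(s$j[order(s$i)])
}

#' @export
print.ssgblup_fit <- function(x, ...) {
  cat(sprintf("<ssgblup_fit> %d records, %d animals (%d genotyped)\n",
              x$meta$n_records, x$meta$n_animals, x$meta$n_genotyped))
  cat(sprintf("  chain %d / burn-in %d / thin %d -> %d samples\n",
              x$meta$chain$length, x$meta$chain$burn_in, x$meta$chain$thin,
              x$meta$n_samples))
  s <- posterior_summary(x$chains$h2)
  cat(sprintf("  h2: mean %.3f, 95%% HPD [%.3f, %.3f]\n",
              s$mean, s$hpd_low, s$hpd_high))
  invisible(x)
}
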