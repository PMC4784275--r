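# recode a pedigree tibble to 1..n integer codes, 0 = unknown parent,
# verifying topological order (every parent precedes its offspring)
ped_codes <- function(ped) {
  if (!all(c("animal", "sire", "dam") %in% names(ped)))
    abort("pedigree needs columns `animal`, `sire`, `dam`")
  if (anyDuplicated(ped$animal))
    abort("duplicated animal ids in pedigree")
  n <- nrow(ped)
  code <- function(parent) {
    idx <- match(parent, ped$animal)
    unknown <- is.na(parent) | parent %in% c(0, "0", "")
    idx[unknown] <- 0L
    if (anyNA(idx)) {
      bad <- unique(parent[is.na(idx) & !unknown])
      abort(paste0("parents absent from pedigree: ",
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
    idx
  }
  sire <- code(ped$sire)
  dam <- code(ped$dam)
  late <- which(sire >= seq_len(n) | dam >= seq_len(n))
  if (length(late))
    abort(sprintf(
      "pedigree is not topologically ordered (cycle or late parent) at animal '%s'",
      as.character(ped$animal[late[1L]])))
  same <- which(sire > 0L & sire == dam)
  if (length(same))
    abort(sprintf("sire equals dam for animal '%s'",
                  as.character(ped$animal[same[1L]])))
  list(sire = sire, dam = dam, ids = as.character(ped$animal), n = n)
}

#' Inbreeding coefficients from a pedigree
#'
#' Meuwissen-Luo style recursion over the gene-flow decomposition
#' A = LDL'; no relationship matrix is formed.
#'
#' @param ped Pedigree tibble (`animal`, `sire`, `dam`), topologically
#'   ordered, `0`/`NA` = unknown parent.
#' @return Named numeric vector of inbreeding coefficients F.
#' @export
inbreeding <- function(ped) {
  codes <- ped_codes(ped)
  setNames(.inbreeding_ml(codes$sire, codes$dam), codes$ids)
}

#' Numerator relationship matrix by the tabular method
#'
#' Direct recursion `a_ij = (a_{j,sire(i)} + a_{j,dam(i)})/2`,
#' `a_ii = 1 + a_{sire,dam}/2`. Quadratic in pedigree size; used as the
#' reference construction for A22 and as an independent check of the
#' sparse inverse.
#'
#' @inheritParams inbreeding
#' @return Dense symmetric matrix A with animal ids as dimnames.
#' @export
build_A_tabular <- function(ped) {
  codes <- ped_codes(ped)
  A <- .tabular_A(codes$sire, codes$dam)
  dimnames(A) <- list(codes$ids, codes$ids)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: for each animal with Mendelian
#' sampling variance `d_i = 0.5 - 0.25 (F_s + F_d)` (0.75 - 0.25 F with one
#' known parent, 1 with none), add `1/d_i` at (i,i), `-1/(2 d_i)` between
#' the animal and each known parent, and `1/(4 d_i)` among known parents.
#' Inbreeding comes from [inbreeding()], so A is never formed.
#'
#' @inheritParams inbreeding
#' @return A sparse symmetric `dgCMatrix` with animal ids as dimnames.
#' @export
build_A_inverse <- function(ped) {
  codes <- ped_codes(ped)
  n <- codes$n
  s <- codes$sire; d <- codes$dam
  Fi <- .inbreeding_ml(s, d)
  Fpad <- c(0, Fi)
  dvec <- 1 - 0.25 * (s > 0L) * (1 + Fpad[s + 1L]) -
              0.25 * (d > 0L) * (1 + Fpad[d + 1L])
  al <- 1 / dvec
  i <- seq_len(n)
  ii <- i; jj <- i; xx <- al
  ks <- which(s > 0L)
  if (length(ks)) {
    ii <- c(ii, ks, s[ks], s[ks])
    jj <- c(jj, s[ks], ks, s[ks])
    xx <- c(xx, -al[ks] / 2, -al[ks] / 2, al[ks] / 4)
  }
  kd <- which(d > 0L)
  if (length(kd)) {
    ii <- c(ii, kd, d[kd], d[kd])
    jj <- c(jj, d[kd], kd, d[kd])
    xx <- c(xx, -al[kd] / 2, -al[kd] / 2, al[kd] / 4)
  }
  kb <- which(s > 0L & d > 0L)
  if (length(kb)) {
    ii <- c(ii, s[kb], d[kb])
    jj <- c(jj, d[kb], s[kb])
    xx <- c(xx, al[kb] / 4, al[kb] / 4)
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(codes$ids, codes$ids))
  Ainv
}

#' Pedigree relationship matrix of the genotyped animals
#'
#' The rows/columns of the tabular A belonging to the genotyped subset.
#'
#' @inheritParams inbreeding
#' @param genotyped_ids Character ids of the genotyped animals (subset of
#'   the pedigree).
#' @return Dense symmetric matrix A22 in the order of `genotyped_ids`.
#' @export
build_A22 <- function(ped, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  idx <- match(genotyped_ids, as.character(ped$animal))
  if (anyNA(idx))
    abort(paste0("genotyped ids absent from pedigree: ",
                 paste(utils::head(genotyped_ids[is.na(idx)], 5), collapse = ", ")))
  A <- build_A_tabular(ped)
  A[idx, idx, drop = FALSE]
}

#' Raw genomic relationship matrix G = Z D Z' / sum 2p(1-p)
#'
#' Gene content is centred at twice the observed allele frequencies
#' (`Z = calls - 2p`), weighted per SNP by `D` (identity in the first
#' weighting round) and scaled by the VanRaden base factor
#' `1 / sum_j 2 p_j (1 - p_j)`.
#'
#' @param geno A post-QC, imputed [geno_matrix()] of genotyped animals.
#' @param weights Non-negative per-SNP weight vector `D` (default all 1).
#' @param p Allele frequencies; default observed frequencies.
#' @return Dense symmetric matrix over the genotyped animals.
#' @export
build_raw_G <- function(geno, weights = NULL, p = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (anyNA(geno$calls))
    abort("missing calls present; run impute_genotypes() after QC")
  if (is.null(p)) p <- allele_freqs(geno)
  if (any(p <= 0 | p >= 1))
    abort("monomorphic SNPs present (p = 0 or 1); run filter_snps() first")
  m <- ncol(geno$calls)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m || any(weights < 0))
    abort("`weights` must be a non-negative vector, one entry per SNP")
  Z <- centered_gene_content(geno, p)
  base <- sum(2 * p * (1 - p))
  Zw <- sweep(Z, 2L, sqrt(weights), `*`)
  G <- tcrossprod(Zw) / base
  (G + t(G)) / 2
}

#' Tune G to the pedigree scale
#'
#' Multiplies G by the scalar `q` that makes its average diagonal equal the
#' average diagonal of A22, aligning the genomic and pedigree relationship
#' scales.
#'
#' @param g_raw Raw genomic relationship matrix.
#' @param a22 Pedigree relationship matrix of the same animals.
#' @return List with `g_tuned` and the scalar `q`.
#' @export
tune_G <- function(g_raw, a22) {
  stopifnot(all(dim(g_raw) == dim(a22)))
  mg <- mean(diag(g_raw))
  if (mg == 0) abort("mean diagonal of raw G is zero; cannot tune")
  q <- mean(diag(a22)) / mg
  list(g_tuned = q * g_raw, q = q)
}

#' Blend G with A22 for invertibility
#'
#' `g_final = (1 - epsilon) g_tuned + epsilon a22`. A small pedigree
#' admixture guarantees a nonsingular G when animals share identical
#' genotypes or markers are few.
#'
#' @param g_tuned Tuned genomic relationship matrix.
#' @param a22 Pedigree relationship matrix of the same animals.
#' @param epsilon Blending fraction in `[0, 1]`, default 0.05.
#' @return Dense symmetric positive-definite matrix.
#' @export
blend_G <- function(g_tuned, a22, epsilon = 0.05) {
  stopifnot(all(dim(g_tuned) == dim(a22)))
  if (epsilon < 0 || epsilon > 1)
    abort("`epsilon` must lie in [0, 1]")
  gf <- (1 - epsilon) * g_tuned + epsilon * a22
  ok <- tryCatch({ chol(gf); TRUE }, error = function(e) FALSE)
  if (!ok)
    abort("blended G is numerically singular; increase `epsilon`")
  gf
}

#' Inverse of the combined pedigree-genomic relationship matrix
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]`: the genotyped block of the
#' sparse pedigree inverse receives the dense correction
#' `G^-1 - A22^-1`. Stored structurally (sparse part + correction block +
#' index), which is what the solver and the Gibbs sampler consume;
#' `as.matrix()` materialises the dense operator.
#'
#' @param a_inv Sparse A inverse over all pedigree animals
#'   ([build_A_inverse()]).
#' @param a22 Pedigree relationship matrix of the genotyped animals.
#' @param g_final Blended, tuned genomic relationship matrix
#'   (same animal order as `a22`).
#' @param genotyped_index Integer positions of the genotyped animals within
#'   the full pedigree ordering (or their character ids).
#' @return An object of class `h_inverse`.
#' @export
build_H_inverse <- function(a_inv, a22, g_final, genotyped_index) {
  n <- nrow(a_inv)
  if (is.character(genotyped_index)) {
    genotyped_index <- match(genotyped_index, rownames(a_inv))
    if (anyNA(genotyped_index))
      abort("genotyped ids not found in A inverse dimnames")
  }
  ng <- length(genotyped_index)
  if (nrow(a22) != ng || nrow(g_final) != ng)
    abort(sprintf("dimension mismatch: %d genotyped indices, a22 %d, g %d",
                  ng, nrow(a22), nrow(g_final)))
  if (any(genotyped_index < 1L | genotyped_index > n))
    abort("genotyped indices outside the pedigree ordering")
  corr <- if (ng) {
    g_inv <- chol2inv(chol(g_final))
    a22_inv <- chol2inv(chol(a22))
    cr <- g_inv - a22_inv
    (cr + t(cr)) / 2
  } else {
    matrix(0, 0, 0)
  }
  structure(list(a_inv = a_inv, correction = corr,
                 index = as.integer(genotyped_index), n = n,
                 ids = rownames(a_inv)),
            class = "h_inverse")
}

#' @export
print.h_inverse <- function(x, ...) {
  cat(sprintf("<h_inverse> %d animals, %d genotyped; sparse A-inverse (%d nnz) + dense correction block\n",
              x$n, length(x$index), Matrix::nnzero(x$a_inv)))
  invisible(x)
}

#' @export
as.matrix.h_inverse <- function(x, ...) {
  H <- as.matrix(x$a_inv)
  if (length(x$index))
    H[x$index, x$index] <- H[x$index, x$index] + x$correction
  H
}

# H^-1 %*% v without materialising the dense operator
h_inv_mult <- function(h_inv, v) {
  out <- as.numeric(h_inv$a_inv %*% v)
  if (length(h_inv$index))
    out[h_inv$index] <- out[h_inv$index] + h_inv$correction %*% v[h_inv$index]
  out
}
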