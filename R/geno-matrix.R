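#' Genotype matrix with SNP map
#'
#' Lightweight container for allele-count genotypes: an animals x SNPs
#' integer matrix of counts in `{0, 1, 2, NA}` (counts of the reference
#' allele) with animal ids as row names, plus a SNP map tibble
#' (`snp_id`, `chrom`, `pos_bp`) with positions strictly increasing within
#' each chromosome.
#'
#' @param calls Integer matrix of allele counts, row names = animal ids.
#' @param map Data frame with columns `snp_id`, `chrom`, `pos_bp`, one row
#'   per column of `calls`, in column order.
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   and `map`.
#' @export
geno_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  map <- as_tibble(map)
  if (is.null(rownames(calls)))
    abort("`calls` must carry animal ids as row names")
  if (!all(c("snp_id", "chrom", "pos_bp") %in% names(map)))
    abort("`map` needs columns snp_id, chrom, pos_bp")
  if (ncol(calls) != nrow(map))
    abort(sprintf("calls has %d columns but map has %d rows",
                  ncol(calls), nrow(map)))
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad))
    abort("genotype calls must be 0, 1, 2 or missing")
  inc <- tapply(map$pos_bp, map$chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(inc)))
    abort("map positions must be strictly increasing within each chromosome")
  colnames(calls) <- map$snp_id
  structure(list(calls = calls, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d animals x %d SNPs on %d chromosome(s), %.2f%% missing\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Observed allele frequencies
#'
#' Frequency of the counted (reference) allele per SNP, computed from the
#' non-missing calls of the animals in the matrix. These are the `p_i` used
#' to centre gene content and to weight SNP variances.
#'
#' @param geno A [geno_matrix()].
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_freqs <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  colMeans(geno$calls, na.rm = TRUE) / 2
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing call with twice the observed allele frequency of
#' its SNP (the column mean) -- the conventional imputation for building a
#' genomic relationship matrix. Run after quality control.
#'
#' @param geno A [geno_matrix()].
#' @return The matrix with no missing calls (imputed values are fractional).
#' @export
impute_genotypes <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  calls <- geno$calls
  storage.mode(calls) <- "double"
  nas <- which(is.na(calls), arr.ind = TRUE)
  if (nrow(nas)) {
    p2 <- colMeans(calls, na.rm = TRUE)
    if (anyNA(p2))
      abort("some SNPs have no observed calls; run filter_snps() first")
    calls[nas] <- p2[nas[, 2L]]
  }
  geno$calls <- calls
  geno
}

#' Subset a genotype matrix
#'
#' @param geno A [geno_matrix()].
#' @param animals Character ids or logical/integer row index; `NULL` keeps all.
#' @param snps Logical/integer column index into the map; `NULL` keeps all.
#' @return A [geno_matrix()] restricted to the selection, map kept in order.
#' @export
subset_geno <- function(geno, animals = NULL, snps = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  calls <- geno$calls
  map <- geno$map
  if (!is.null(animals)) {
    if (is.character(animals)) {
      missing_ids <- setdiff(animals, rownames(calls))
      if (length(missing_ids))
        abort(paste0("unknown animal ids: ",
                     paste(utils::head(missing_ids, 5), collapse = ", ")))
    }
    calls <- calls[animals, , drop = FALSE]
  }
  if (!is.null(snps)) {
    calls <- calls[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
  }
  out <- geno_matrix(calls, map)
  attr(out, "truth") <- attr(geno, "truth")
  out
}

# centred gene content Z = calls - 2p; requires imputed (no NA) calls
centered_gene_content <- function(geno, p = NULL) {
  if (anyNA(geno$calls))
    abort("missing calls present; impute_genotypes() first")
  if (is.null(p)) p <- allele_freqs(geno)
  sweep(geno$calls, 2L, 2 * p)
}
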