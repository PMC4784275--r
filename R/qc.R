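#' Quality-control thresholds
#'
#' Marker and phenotype filters applied before model fitting: markers with
#' unknown position or on excluded chromosomes, low call rate, monomorphic,
#' low minor allele frequency, or excess heterozygosity are removed (in
#' that fixed order, each SNP attributed to the first filter it fails),
#' then samples with low call rate; contemporary groups smaller than
#' `min_cg_size` are dropped whole, then records deviating
#' `cg_sd_limit` or more group standard deviations from their group mean.
#'
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @param min_snp_call_rate Minimum per-SNP call rate (default 0.90).
#' @param min_sample_call_rate Minimum per-sample call rate (default 0.90).
#' @param het_excess_limit Maximum absolute excess of observed over
#'   Hardy-Weinberg expected heterozygosity `2p(1-p)` (default 0.15).
#' @param excluded_chromosomes Chromosome labels removed outright; default
#'   the sex chromosomes and the unknown label `"0"`.
#' @param min_cg_size Minimum contemporary-group size (default 3).
#' @param cg_sd_limit Outlier limit in group standard deviations
#'   (default 3).
#' @return An object of class `qc_thresholds` (a validated list).
#' @export
qc_thresholds <- function(min_maf = 0.05,
                          min_snp_call_rate = 0.90,
                          min_sample_call_rate = 0.90,
                          het_excess_limit = 0.15,
                          excluded_chromosomes = c("X", "Y", "0"),
                          min_cg_size = 3L,
                          cg_sd_limit = 3) {
  thr <- list(min_maf = min_maf, min_snp_call_rate = min_snp_call_rate,
              min_sample_call_rate = min_sample_call_rate,
              het_excess_limit = het_excess_limit,
              excluded_chromosomes = as.character(excluded_chromosomes),
              min_cg_size = as.integer(min_cg_size),
              cg_sd_limit = cg_sd_limit)
  fr <- c("min_maf", "min_snp_call_rate", "min_sample_call_rate", "het_excess_limit")
  for (f in fr)
    if (thr[[f]] < 0 || thr[[f]] > 1)
      abort(sprintf("`%s` must lie in [0, 1]", f))
  if (thr$min_cg_size < 1L) abort("`min_cg_size` must be positive")
  if (thr$cg_sd_limit <= 0) abort("`cg_sd_limit` must be positive")
  structure(thr, class = "qc_thresholds")
}

#' Filter SNPs and samples
#'
#' Fixed filter order: (1) unknown position / excluded chromosome,
#' (2) SNP call rate, (3) monomorphic, (4) MAF, (5) heterozygosity excess,
#' then (6) sample call rate computed on the surviving SNPs. Each SNP is
#' attributed to the first filter it fails; surviving rows and columns keep
#' their input order, so the surviving set is invariant to SNP shuffling.
#'
#' @param geno A [geno_matrix()].
#' @param thr A [qc_thresholds()].
#' @return List with the filtered `geno` and a `report` tibble
#'   (`filter`, `axis`, `n_removed`) plus surviving dimensions in
#'   `attr(report, "surviving")`.
#' @export
filter_snps <- function(geno, thr = qc_thresholds()) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(thr, "qc_thresholds"))
  calls <- geno$calls
  map <- geno$map
  m <- ncol(calls)
  n <- nrow(calls)

  alive <- rep(TRUE, m)
  removed <- integer(0)

  fail_chrom <- is.na(map$pos_bp) | map$chrom %in% thr$excluded_chromosomes
  n_chrom <- sum(fail_chrom & alive)
  alive <- alive & !fail_chrom

  call_rate <- colMeans(!is.na(calls))
  fail_cr <- call_rate < thr$min_snp_call_rate
  n_cr <- sum(fail_cr & alive)
  alive <- alive & !fail_cr

  p <- colMeans(calls, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0 # all-missing columns were caught by call rate
  fail_mono <- p <= 0 | p >= 1
  n_mono <- sum(fail_mono & alive)
  alive <- alive & !fail_mono

  maf <- pmin(p, 1 - p)
  fail_maf <- maf < thr$min_maf
  n_maf <- sum(fail_maf & alive)
  alive <- alive & !fail_maf

  obs_het <- colMeans(calls == 1L, na.rm = TRUE)
  exp_het <- 2 * p * (1 - p)
  fail_het <- (obs_het - exp_het) > thr$het_excess_limit
  n_het <- sum(fail_het & alive, na.rm = TRUE)
  alive <- alive & !fail_het

  if (!any(alive))
    abort("no SNPs survive QC", class = "wssgwas_qc_error")

  surv <- calls[, alive, drop = FALSE]
  sample_cr <- rowMeans(!is.na(surv))
  keep_sample <- sample_cr >= thr$min_sample_call_rate
  n_sample <- sum(!keep_sample)
  surv <- surv[keep_sample, , drop = FALSE]
  if (nrow(surv) == 0L)
    abort("no samples survive QC", class = "wssgwas_qc_error")

  report <- tibble(
    filter = c("excluded_chromosome", "snp_call_rate", "monomorphic",
               "maf", "het_excess", "sample_call_rate"),
    axis = c(rep("snp", 5L), "sample"),
    n_removed = c(n_chrom, n_cr, n_mono, n_maf, n_het, n_sample)
  )
  attr(report, "surviving") <- c(samples = nrow(surv), snps = ncol(surv))

  out <- geno_matrix(surv, map[alive, , drop = FALSE])
  attr(out, "truth") <- attr(geno, "truth")
  list(geno = out, report = report)
}

#' Filter contemporary groups and outlying records
#'
#' Whole groups with fewer than `min_cg_size` records are removed; then, in
#' a single pass, records whose absolute deviation from their group mean
#' reaches `cg_sd_limit` group standard deviations are removed (mean and SD
#' computed on the pre-drop group; the SD is the population SD, divide by
#' n). Groups with zero variance undergo no outlier removal.
#'
#' @param phen Phenotype tibble with columns `trait_value` and `cg`.
#' @param thr A [qc_thresholds()].
#' @return List with the filtered `phen` and a `report` tibble.
#' @export
filter_contemporary_groups <- function(phen, thr = qc_thresholds()) {
  stopifnot(inherits(thr, "qc_thresholds"))
  if (!all(c("trait_value", "cg") %in% names(phen)))
    abort("phenotypes need columns `trait_value` and `cg`")
  truth <- attr(phen, "truth")
  cg <- as.character(phen$cg)
  sizes <- table(cg)
  small <- names(sizes)[sizes < thr$min_cg_size]
  keep1 <- !(cg %in% small)
  n_small <- sum(!keep1)

  d1 <- phen[keep1, , drop = FALSE]
  cg1 <- cg[keep1]
  grp_mean <- tapply(d1$trait_value, cg1, mean)
  grp_sd <- tapply(d1$trait_value, cg1, function(v)
    sqrt(mean((v - mean(v))^2)))
  dev <- abs(d1$trait_value - grp_mean[cg1])
  lim <- thr$cg_sd_limit * grp_sd[cg1]
  outlier <- grp_sd[cg1] > 0 & dev >= lim * (1 - 1e-12)
  n_out <- sum(outlier)
  out_phen <- d1[!outlier, , drop = FALSE]

  report <- tibble(
    filter = c("small_cg", "cg_outlier"),
    axis = "record",
    n_removed = c(n_small, n_out)
  )
  attr(report, "surviving") <- c(records = nrow(out_phen))
  if (!is.null(truth)) attr(out_phen, "truth") <- truth
  list(phen = out_phen, report = report)
}
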