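# shared fixture builders; everything is generated in code

# founders + random-mating generations; ~450 animals, 1000 SNPs by default
small_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    n_founders = 150L, n_generations = 2L, n_matings = 75L,
    offspring_per_mating = 2L, n_chromosomes = 5L, snps_per_chromosome = 200L,
    prop_genotyped = 0.6, h2 = 0.3, seed = seed), list(...))
  do.call(sim_config, args)
}

# study-scale configuration: 1500 animals (800 genotyped), 3000 SNPs
study_cfg <- function(seed = 1L, ...) {
  do.call(sim_config, utils::modifyList(list(seed = seed), list(...)))
}

# sire-dam-offspring trio, non-inbred
trio_ped <- function() {
  tibble::tibble(animal = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
}

# tiny genotype container from an explicit call matrix (one chromosome)
make_geno <- function(calls, chrom = NULL, pos = NULL) {
  m <- ncol(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("A%d", seq_len(nrow(calls)))
  map <- tibble::tibble(
    snp_id = sprintf("S%03d", seq_len(m)),
    chrom = if (is.null(chrom)) rep("1", m) else chrom,
    pos_bp = if (is.null(pos)) as.integer(seq_len(m) * 1000L) else as.integer(pos))
  geno_matrix(calls, map)
}

# simulated data bundle ready for model fitting
sim_bundle <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  geno <- drop_genotypes(ped, cfg)
  phen <- simulate_phenotypes(ped, geno, cfg)
  qc <- filter_snps(geno)
  gi <- impute_genotypes(qc$geno)
  design <- build_design_matrices(phen, ped)
  list(cfg = cfg, ped = ped, geno = geno, phen = phen, gi = gi,
       design = design,
       a_inv = build_A_inverse(ped),
       a22 = build_A22(ped, rownames(gi$calls)),
       gidx = match(rownames(gi$calls), as.character(ped$animal)))
}

# window index containing a given snp id within a window report
window_of <- function(report, snp_id) {
  which(mapply(function(s, e) snp_id >= s & snp_id <= e,
               report$start_snp, report$end_snp))[1]
}

# 25 animals, 6 SNPs: one column per QC filter plus two clean columns
six_snp_fixture <- function() {
  n <- 25L
  clean1 <- rep(c(0L, 1L, 2L, 1L, 0L), 5)          # p = 0.4
  clean2 <- rep(c(2L, 1L, 0L, 1L, 2L), 5)          # p = 0.6
  on_x <- rep(c(0L, 1L), length.out = n)           # excluded chromosome
  half_missing <- clean1; half_missing[1:13] <- NA # call rate 12/25 < 0.9
  mono <- rep(2L, n)                               # monomorphic
  rare <- c(1L, rep(0L, n - 1L))                   # MAF = 1/50 = 0.02
  calls <- cbind(on_x, half_missing, mono, rare, clean1, clean2)
  rownames(calls) <- sprintf("A%02d", 1:n)
  make_geno(calls, chrom = c("X", "1", "1", "1", "1", "1"))
}
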