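#' Simulate a multi-generation random-mating pedigree
#'
#' Generation 0 holds `n_founders` unrelated animals with unknown parents.
#' Each later generation is produced by `n_matings` matings, each between a
#' sire and a distinct dam sampled uniformly (with replacement across
#' matings) from the previous generation, each producing
#' `offspring_per_mating` offspring. There is no selection and no
#' overlapping generations, so the pedigree is topologically ordered by
#' construction.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `animal`, `sire`, `dam`, `generation`;
#'   `0` marks an unknown parent. Deterministic given `cfg$seed`.
#' @export
simulate_pedigree <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  withr::with_seed(cfg$seed, {
    animal <- seq_len(cfg$n_founders)
    sire <- dam <- rep(0L, cfg$n_founders)
    generation <- rep(0L, cfg$n_founders)
    prev <- animal
    next_id <- cfg$n_founders + 1L
    if (cfg$n_generations > 0L && length(prev) < 2L)
      abort("need at least 2 founders to breed", class = "wssgwas_config_error")
    for (g in seq_len(cfg$n_generations)) {
      gs <- gd <- integer(cfg$n_matings)
      for (mtg in seq_len(cfg$n_matings)) {
        pair <- sample(prev, 2L)
        gs[mtg] <- pair[1L]
        gd[mtg] <- pair[2L]
      }
      n_off <- cfg$n_matings * cfg$offspring_per_mating
      ids <- seq.int(next_id, length.out = n_off)
      animal <- c(animal, ids)
      sire <- c(sire, rep(gs, each = cfg$offspring_per_mating))
      dam <- c(dam, rep(gd, each = cfg$offspring_per_mating))
      generation <- c(generation, rep.int(g, n_off))
      prev <- ids
      next_id <- next_id + n_off
    }
    tibble(animal = animal, sire = sire, dam = dam, generation = generation)
  })
}

#' Drop genotypes through a pedigree
#'
#' Gene dropping: founder allele frequencies are drawn per SNP from
#' `Uniform(founder_maf_range)`, founders are sampled from Hardy-Weinberg
#' proportions at those frequencies, and every non-founder receives one
#' allele from each parent by Mendelian transmission (a heterozygous parent
#' transmits either allele with probability 1/2). SNPs are transmitted
#' independently (linkage equilibrium; no recombination map). An unknown
#' parent's allele is sampled from the founder frequency of that SNP. The
#' youngest `prop_genotyped` fraction of animals is marked genotyped; only
#' their calls are returned, with a `missing_rate` fraction blanked.
#'
#' @param ped Pedigree tibble (`animal`, `sire`, `dam`), topologically
#'   ordered.
#' @param cfg A [sim_config()].
#' @return A [geno_matrix()] of the genotyped animals. For downstream truth
#'   checks, `attr(, "truth")` carries the complete un-blanked call matrix
#'   of all animals (`true_calls`), the founder frequencies
#'   (`founder_freq`), and the genotyped ids.
#' @export
drop_genotypes <- function(ped, cfg) {
  cfg <- validate_sim_config(cfg)
  codes <- ped_codes(ped)
  n <- nrow(ped)
  m <- cfg$n_chromosomes * cfg$snps_per_chromosome
  withr::with_seed(cfg$seed + 1L, {
    p0 <- runif(m, cfg$founder_maf_range[1L], cfg$founder_maf_range[2L])
    map <- tibble(
      snp_id = sprintf("SNP%05d", seq_len(m)),
      chrom = rep(as.character(seq_len(cfg$n_chromosomes)),
                  each = cfg$snps_per_chromosome),
      pos_bp = as.vector(vapply(seq_len(cfg$n_chromosomes), function(cc)
        sort(sample.int(cfg$chrom_length_bp, cfg$snps_per_chromosome)),
        integer(cfg$snps_per_chromosome)))
    )
    calls <- matrix(0L, n, m, dimnames = list(as.character(ped$animal), NULL))
    for (i in seq_len(n)) {
      s <- codes$sire[i]; d <- codes$dam[i]
      if (s == 0L && d == 0L) {
        calls[i, ] <- rbinom(m, 2L, p0)
      } else {
        a1 <- if (s > 0L) transmit_allele(calls[s, ]) else rbinom(m, 1L, p0)
        a2 <- if (d > 0L) transmit_allele(calls[d, ]) else rbinom(m, 1L, p0)
        calls[i, ] <- a1 + a2
      }
    }
    n_geno <- round(cfg$prop_genotyped * n)
    geno_rows <- if (n_geno > 0L) seq.int(n - n_geno + 1L, n) else integer(0)
    observed <- calls[geno_rows, , drop = FALSE]
    if (cfg$missing_rate > 0 && length(observed)) {
      blank <- runif(length(observed)) < cfg$missing_rate
      observed[blank] <- NA_integer_
    }
    out <- geno_matrix(observed, map)
    attr(out, "truth") <- list(true_calls = calls, founder_freq = p0,
                               genotyped = rownames(observed))
    out
  })
}

# one gamete from a parent's allele-count vector
transmit_allele <- function(parent_calls) {
  het <- parent_calls == 1L
  al <- as.integer(parent_calls == 2L)
  if (any(het)) al[het] <- rbinom(sum(het), 1L, 0.5)
  al
}

#' Simulate phenotypes over a pedigree
#'
#' Builds `trait = CG effect + b1*age + b2*age^2 + polygenic + QTL +
#' residual`. The polygenic value follows the standard pedigree recursion
#' (child = half sire + half dam + Mendelian-sampling deviation, with the
#' sampling variance reduced by parental inbreeding); QTL contributions are
#' `beta_q * (true call - mean)` with `beta_q` scaled so each QTL explains
#' exactly its requested fraction of the additive variance in this sample.
#' The phenotypic variance is targeted at 1, so `sigma2_a = h2` and
#' `sigma2_e = 1 - h2`. Every animal receives one record.
#'
#' @param ped Pedigree tibble, topologically ordered.
#' @param geno A [geno_matrix()] from [drop_genotypes()] (needed only when
#'   `cfg$qtl_spec` is set; QTL effects use the true gene content of all
#'   animals from its truth side-channel).
#' @param cfg A [sim_config()].
#' @return A tibble (`animal_id`, `trait_value`, `cg`, `age`) with a
#'   `truth` attribute: a tibble of per-animal true breeding values
#'   (`tbv`, split into `polygenic` and `qtl`) and the fixed part of each
#'   record, plus the true variance components.
#' @export
simulate_phenotypes <- function(ped, geno = NULL, cfg) {
  cfg <- validate_sim_config(cfg)
  codes <- ped_codes(ped)
  n <- nrow(ped)
  sigma2_a <- cfg$h2
  sigma2_e <- 1 - cfg$h2
  qtl_frac <- if (is.null(cfg$qtl_spec)) 0 else sum(cfg$qtl_spec$frac)
  sigma2_poly <- (1 - qtl_frac) * sigma2_a
  withr::with_seed(cfg$seed + 2L, {
    # polygenic values by pedigree recursion
    polygenic <- numeric(n)
    if (sigma2_poly > 0) {
      Fi <- c(0, .inbreeding_ml(codes$sire, codes$dam)) # pad for code 0
      z <- rnorm(n)
      for (i in seq_len(n)) {
        s <- codes$sire[i]; d <- codes$dam[i]
        if (s == 0L && d == 0L) {
          polygenic[i] <- z[i] * sqrt(sigma2_poly)
        } else {
          pm <- (if (s > 0L) polygenic[s] else 0) + (if (d > 0L) polygenic[d] else 0)
          dvar <- 1 - 0.25 * (s > 0L) * (1 + Fi[s + 1L]) -
                      0.25 * (d > 0L) * (1 + Fi[d + 1L])
          polygenic[i] <- 0.5 * pm + z[i] * sqrt(dvar * sigma2_poly)
        }
      }
    }
    # major QTL from true gene content
    qtl <- numeric(n)
    if (!is.null(cfg$qtl_spec) && qtl_frac > 0) {
      truth_g <- attr(geno, "truth")
      if (is.null(truth_g))
        abort("`geno` must come from drop_genotypes() when QTL are requested")
      for (k in seq_len(nrow(cfg$qtl_spec))) {
        j <- cfg$qtl_spec$snp[k]
        zq <- truth_g$true_calls[, j]
        vq <- var(zq)
        if (vq == 0)
          abort(sprintf("QTL SNP %d is monomorphic in this population", j))
        qtl <- qtl + sqrt(cfg$qtl_spec$frac[k] * sigma2_a / vq) * (zq - mean(zq))
      }
    }
    tbv <- polygenic + qtl

    cg_w <- (1 + cfg$cg_imbalance)^(seq_len(cfg$n_contemporary_groups) - 1L)
    cg <- sample.int(cfg$n_contemporary_groups, n, replace = TRUE,
                     prob = cg_w / sum(cg_w))
    cg_eff <- rnorm(cfg$n_contemporary_groups, 0, cfg$cg_sd)
    age <- round(runif(n, cfg$age_range[1L], cfg$age_range[2L]))
    fixed <- cg_eff[cg] + cfg$beta_age[1L] * age + cfg$beta_age[2L] * age^2
    e <- if (sigma2_e > 0) rnorm(n, 0, sqrt(sigma2_e)) else numeric(n)

    phen <- tibble(
      animal_id = ped$animal,
      trait_value = fixed + tbv + e,
      cg = factor(paste0("CG", cg),
                  levels = paste0("CG", seq_len(cfg$n_contemporary_groups))),
      age = age
    )
    attr(phen, "truth") <- list(
      values = tibble(animal_id = ped$animal, tbv = tbv,
                      polygenic = polygenic, qtl = qtl, fixed = fixed),
      sigma2_a = sigma2_a, sigma2_e = sigma2_e, h2 = cfg$h2,
      cg_effects = cg_eff, beta_age = cfg$beta_age
    )
    phen
  })
}
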