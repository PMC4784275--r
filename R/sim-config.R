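#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study generator: a discrete
#' multi-generation pedigree, biallelic SNPs on several chromosomes dropped
#' through the pedigree, and phenotypes built from contemporary-group
#' effects, a linear + quadratic slaughter-age covariate, a pedigree-driven
#' polygenic value, optional major QTL, and environmental noise. Defaults
#' emulate a beef-cattle carcass-trait design: ~1,500 recorded animals of
#' which roughly half (the youngest) are genotyped, 3,000 SNPs on 10
#' chromosomes, moderate heritability.
#'
#' @param n_founders Number of unrelated founder animals (generation 0).
#' @param n_generations Number of offspring generations bred after the
#'   founders. `0` gives a founders-only pedigree.
#' @param n_matings Matings per generation; each mating samples a sire and a
#'   distinct dam from the previous generation.
#' @param offspring_per_mating Offspring produced by each mating.
#' @param n_chromosomes,snps_per_chromosome,chrom_length_bp Marker map:
#'   `snps_per_chromosome` SNPs placed at distinct, increasing positions on
#'   each of `n_chromosomes` chromosomes of `chrom_length_bp` base pairs.
#' @param prop_genotyped Fraction of animals marked genotyped; the youngest
#'   animals are genotyped first, as in real cattle cohorts.
#' @param h2 Target narrow-sense heritability in `[0,1]`; the phenotypic
#'   variance is scaled to 1, so `sigma2_a = h2` and `sigma2_e = 1 - h2`.
#' @param qtl_spec Optional QTL specification: a data frame (or tibble) with
#'   columns `snp` (column index into the marker map) and `frac` (fraction
#'   of the total additive genetic variance explained). Fractions must sum
#'   to at most 1; the remainder is polygenic.
#' @param n_contemporary_groups Number of contemporary groups (farm x year x
#'   management classes).
#' @param cg_imbalance Imbalance of group sizes: animals are assigned to
#'   group k with probability proportional to `(1 + cg_imbalance)^(k-1)`;
#'   `0` gives (stochastically) equal groups.
#' @param age_range Slaughter-age range in days, `c(min, max)`.
#' @param founder_maf_range Range of the uniform distribution founder allele
#'   frequencies are drawn from; the default `c(0.1, 0.9)` keeps post-QC
#'   marker retention high.
#' @param missing_rate Fraction of observed genotype calls blanked to
#'   missing, to exercise call-rate QC and mean imputation.
#' @param beta_age Linear and quadratic slaughter-age regression
#'   coefficients (trait units per day and per day squared).
#' @param cg_sd Standard deviation of the simulated contemporary-group
#'   effects (trait units).
#' @param seed Integer seed; all three simulation stages are deterministic
#'   given the seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_pedigree()], [drop_genotypes()], [simulate_phenotypes()]
#' @export
sim_config <- function(n_founders = 300,
                       n_generations = 3,
                       n_matings = 100,
                       offspring_per_mating = 4,
                       n_chromosomes = 10,
                       snps_per_chromosome = 300,
                       chrom_length_bp = 1e8,
                       prop_genotyped = 800 / 1500,
                       h2 = 0.3,
                       qtl_spec = NULL,
                       n_contemporary_groups = 20,
                       cg_imbalance = 0.1,
                       age_range = c(600, 750),
                       founder_maf_range = c(0.1, 0.9),
                       missing_rate = 0.01,
                       beta_age = c(0.02, -2e-5),
                       cg_sd = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_matings = as.integer(n_matings),
    offspring_per_mating = as.integer(offspring_per_mating),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chrom_length_bp = as.integer(chrom_length_bp),
    prop_genotyped = prop_genotyped,
    h2 = h2,
    qtl_spec = if (!is.null(qtl_spec)) as_tibble(qtl_spec) else NULL,
    n_contemporary_groups = as.integer(n_contemporary_groups),
    cg_imbalance = cg_imbalance,
    age_range = age_range,
    founder_maf_range = founder_maf_range,
    missing_rate = missing_rate,
    beta_age = beta_age,
    cg_sd = cg_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  pos <- c("n_founders", "n_chromosomes", "snps_per_chromosome",
           "chrom_length_bp", "offspring_per_mating", "n_contemporary_groups")
  for (f in pos) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      abort(sprintf("`%s` must be a positive count", f), class = "wssgwas_config_error")
  }
  for (f in c("n_generations", "n_matings")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 0L)
      abort(sprintf("`%s` must be a non-negative count", f), class = "wssgwas_config_error")
  }
  if (cfg$n_generations > 0L && cfg$n_matings < 1L)
    abort("`n_matings` must be positive when generations are bred",
          class = "wssgwas_config_error")
  if (cfg$h2 < 0 || cfg$h2 > 1)
    abort("`h2` must lie in [0, 1]", class = "wssgwas_config_error")
  if (cfg$prop_genotyped < 0 || cfg$prop_genotyped > 1)
    abort("`prop_genotyped` must lie in [0, 1]", class = "wssgwas_config_error")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    abort("`missing_rate` must lie in [0, 1)", class = "wssgwas_config_error")
  if (!is.null(cfg$qtl_spec)) {
    if (!all(c("snp", "frac") %in% names(cfg$qtl_spec)))
      abort("`qtl_spec` needs columns `snp` and `frac`", class = "wssgwas_config_error")
    if (any(cfg$qtl_spec$frac < 0) || sum(cfg$qtl_spec$frac) > 1 + 1e-12)
      abort("QTL variance fractions must be non-negative and sum to at most 1",
            class = "wssgwas_config_error")
    m <- cfg$n_chromosomes * cfg$snps_per_chromosome
    if (any(cfg$qtl_spec$snp < 1) || any(cfg$qtl_spec$snp > m))
      abort("`qtl_spec$snp` indices fall outside the marker map",
            class = "wssgwas_config_error")
  }
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) < 0 || any(cfg$age_range <= 0))
    abort("`age_range` must be positive and ordered (min, max)",
          class = "wssgwas_config_error")
  if (length(cfg$founder_maf_range) != 2L ||
      any(cfg$founder_maf_range <= 0) || any(cfg$founder_maf_range >= 1))
    abort("`founder_maf_range` must lie strictly inside (0, 1)",
          class = "wssgwas_config_error")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  n_off <- x$n_generations * x$n_matings * x$offspring_per_mating
  cat("<sim_config>\n")
  cat(sprintf("  pedigree: %d founders + %d generations x %d matings x %d offspring = %d animals\n",
              x$n_founders, x$n_generations, x$n_matings,
              x$offspring_per_mating, x$n_founders + n_off))
  cat(sprintf("  markers:  %d chromosomes x %d SNPs\n",
              x$n_chromosomes, x$snps_per_chromosome))
  cat(sprintf("  h2 = %.2f, %d QTL, prop genotyped = %.2f, seed = %d\n",
              x$h2, if (is.null(x$qtl_spec)) 0L else nrow(x$qtl_spec),
              x$prop_genotyped, x$seed))
  invisible(x)
}
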