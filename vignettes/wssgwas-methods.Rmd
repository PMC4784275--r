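---
title: "Weighted single-step GWAS: models, choices and limits"
author: "wssgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GWAS: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wssgwas)
```

## The problem

In many livestock cohorts only a fraction of the pedigreed, phenotyped
animals is genotyped. Single-step genomic BLUP (ssGBLUP) evaluates all
animals jointly by replacing the pedigree relationship matrix with a
combined pedigree–genomic matrix, and its GWAS extension ("weighted
ssGWAS") converts the resulting genomic breeding values (GEBVs) into
per-SNP effects, re-weights SNPs by the variance they explain, and reports
the percentage of additive genetic variance captured by windows of
adjacent SNPs. This package implements that pipeline end to end — data
simulation, quality control, relationship matrices, Bayesian variance
components, the weighting loop, window decomposition and gene annotation —
for a beef-cattle-style design: roughly 1,500 recorded animals, half of
them genotyped, moderately heritable carcass or fatty-acid-type traits.

## The model

The trait model is the univariate animal model

$$ y = X\beta + Za + e, \qquad
   a \sim N(0,\, \sigma^2_a H), \qquad
   e \sim N(0,\, \sigma^2_e I), $$

with fixed effects $\beta$ = contemporary group (farm × year × management)
plus slaughter age as a linear and quadratic covariate, and $a$ the
additive genetic values of *all* pedigree animals. The combined
relationship matrix enters through its inverse,

$$ H^{-1} = A^{-1} +
   \begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1} \end{bmatrix}, $$

where $A^{-1}$ is the sparse pedigree inverse (Henderson's rules with
inbreeding from the Meuwissen–Luo recursion), $A_{22}$ the pedigree
relationships of the genotyped animals, and $G$ the genomic relationship
matrix

$$ G = \frac{Z_c D Z_c'}{\sum_j 2p_j(1-p_j)} \cdot q, $$

built from gene content $Z_c$ centred at twice the observed allele
frequencies, a per-SNP weight matrix $D$ (identity in the first round),
and the scalar $q$ that matches the average diagonal of $G$ to that of
$A_{22}$. Before inversion, $G$ is blended with $A_{22}$:
$G^* = (1-\varepsilon)\,qG + \varepsilon A_{22}$, $\varepsilon = 0.05$ by
default. The blending step is a numerical-invertibility device (a $G$
centred at observed frequencies is always rank-deficient); it is reported
in the fitted objects and configurable down to 0.

### Variance components

`gibbs_fit()` samples the model by single-site Gibbs: flat priors on
$\beta$, scaled inverse chi-square priors (the univariate inverted
Wishart) on both variances, normal full conditionals for every location
effect, and scaled inverse chi-square full conditionals for
$\sigma^2_a$ (via $a'H^{-1}a$) and $\sigma^2_e$ (via $e'e$). Defaults:
degrees of freedom 4 for both variance priors, scales set from an
ANOVA-style split of the fixed-effect-adjusted phenotypic variance (half
additive, half residual). Two consequences of that prior are worth
knowing: it is weakly informative in the interior, but its density
vanishes at zero variance, so under a true $h^2 = 0$ the posterior
concentrates just *above* the boundary (HPD lower bound ≈ 0.04 in our
null experiments) rather than on it.

The default chain is 50,000 iterations, 5,000 burn-in, thinning 10 — a
desk-scale setting that recovers a true $h^2 = 0.30$ within ±0.06 at the
default problem size; production-scale chains (e.g. 1,000,000 / 80,000 /
100) are a configuration change. Heritability is computed per posterior
sample as $\sigma^2_a/(\sigma^2_a+\sigma^2_e)$ and summarised by mean,
median, SD and the highest-posterior-density interval (shortest interval
containing the requested mass of sorted samples). Convergence checks:
`geweke_diag()` (first 10% vs last 50% means, batch-means variances with
$\lceil\sqrt n\rceil$ batches) and `heidelberger_welch_diag()`
(Cramér–von Mises stationarity test on the Brownian-bridge transform,
discarding successive 10% prefixes; spectral density at zero from a
Yule–Walker AR fit on the second half of the tested suffix, so a level
shift cannot mask itself; then the relative halfwidth test).

### From GEBVs to SNP windows

The weighting loop (`run_weighted_iterations()`) repeats:

1. rebuild $G$ with the current weights $D$, tune, blend, rebuild $H^{-1}$;
2. recompute GEBVs by the exact mixed-model solve at the (fixed) variance
   components;
3. back-solve SNP effects
   $\hat u = D Z_c' [Z_c D Z_c']^{-1} \hat a_g$;
4. set $d_i = \hat u_i^2\, 2p_i(1-p_i)$ and rescale so
   $\sum_i d_i\,2p_i(1-p_i)$ keeps its $D = I$ value (total genetic
   variance is conserved).

Two rounds are the default. The variance components are estimated once by
Gibbs and frozen during the loop; re-estimation per round is possible by
calling the stages manually.

One algebraic subtlety is handled explicitly. Because $Z_c$ is centred at
the observed allele frequencies, its columns sum to zero and
$Z_c D Z_c'$ has an exact rank-one null space along the vector of ones:
no combination of marker effects can reproduce the genotyped-group *mean*
GEBV, only the deviations from it. `backsolve_snp_effects()` therefore
inverts the operator on its range (a symmetric-eigenvalue pseudo-inverse)
and returns the group-mean constant as `attr(u, "base")`; the
reconstruction $Z_c\hat u + \text{base} = \hat a_g$ holds to machine
precision at every iteration, which is what the test suite asserts. The
base constant is irrelevant to window variances, which are shift-free.

Windows are non-overlapping blocks of 10 map-consecutive SNPs within each
chromosome (a trailing remainder is kept as a short window, visible via
`n_snps`); each window's report is
$100 \cdot \mathrm{Var}(\sum_{j\in w} Z_j\hat u_j)/\sigma^2_a$, the
variance taken across genotyped animals and $\sigma^2_a$ the posterior
mean from the initial fit. Windows at or above 1% are selected (the
threshold is exposed; results quoting "more than 1%" are the same set in
practice) and can be annotated against any local GFF3 gene set with
`annotate_regions()` (closed-interval, 1-based overlap; strand ignored;
a configurable flank covers "close to" genes; windows without genes keep
`NA` gene columns).

## The synthetic cohort

`sim_config()` + `simulate_pedigree()` + `drop_genotypes()` +
`simulate_phenotypes()` generate the full study design with known truth:

* **Pedigree** — founders plus discrete generations of random matings
  (no selection, no overlapping generations). Defaults: 300 founders,
  3 generations × 100 matings × 4 offspring = 1,500 animals.
* **Genotypes** — founder allele frequencies Uniform(0.1, 0.9) (so
  post-QC retention is high), Hardy–Weinberg founders, Mendelian gene
  dropping with SNPs transmitted independently. The youngest animals are
  genotyped (800 by default), emulating the usual age structure of
  genotyping; 1% of calls are blanked to exercise call-rate QC and mean
  imputation.
* **Phenotypes** — contemporary-group effect (group sizes mildly
  imbalanced, assignment probability $\propto 1.1^{k-1}$), a linear +
  quadratic age covariate over a 600–750-day slaughter window, a
  polygenic value simulated by the pedigree recursion (child = parent
  average + Mendelian-sampling deviation, reduced by parental
  inbreeding), optional major QTL whose effects are scaled against the
  realised gene-content variance so each explains exactly its requested
  fraction of $\sigma^2_a$, and Gaussian residual. The phenotypic
  variance is 1, so $\sigma^2_a = h^2$.

What the generator deliberately does **not** emulate: linkage
disequilibrium (no recombination map; SNPs are independent), selection,
assortative mating, multi-trait structure, genotyping error. Passing
tests on these data therefore demonstrate the algebra and the estimation
machinery, not the mapping resolution one would obtain on a real LD
panel — see the limitations below.

## Quality control

`filter_snps()` applies, in a fixed, logged order: excluded chromosome /
unknown position, SNP call rate < 0.90, monomorphic, MAF < 0.05,
heterozygosity excess, then sample call rate < 0.90 on the surviving
SNPs. Each SNP is attributed to the first filter it fails, so removal
counts are unambiguous and the surviving set is invariant to SNP order.
"Excess heterozygosity" is undefined in most chip-QC write-ups; here it
is an absolute excess of observed over Hardy–Weinberg expected
heterozygosity greater than 0.15, configurable. Missing calls are imputed
*after* QC as twice the observed allele frequency — the conventional mean
imputation for building $G$.

`filter_contemporary_groups()` removes whole groups with fewer than 3
records, then (single pass, statistics from the pre-drop group) records
deviating 3 or more group standard deviations from their group mean. The
SD is the population (divide-by-$n$) SD and the limit is inclusive — the
reading under which a 10-record group holding nine zeros and one 100
loses exactly the 100. Zero-variance groups see no outlier removal.

## Numerical choices

* $A^{-1}$ is assembled from vectorised Henderson triplets with
  inbreeding from a compiled Meuwissen–Luo recursion; the tabular-method
  $A$ (also compiled) serves as the independent cross-check and supplies
  $A_{22}$.
* The Gibbs core is compiled and exploits the sparse-plus-dense-block
  structure of $H^{-1}$, maintaining $H^{-1}a$ incrementally with a
  periodic refresh against floating-point drift; it uses R's RNG stream,
  so `set.seed()`-style reproducibility holds exactly.
* The direct solver materialises the mixed-model equations densely
  (cohorts here are a few thousand equations) and checks the linear
  residual.
* Pseudo-inverse tolerance for the backsolve: eigenvalues below
  $10^{-10}$ of the largest are treated as null space.
* Window variances use the sample variance across genotyped animals
  (denominator $n-1$); ties in region selection break by chromosome then
  position.

Problem sizes used by the test suite: the heritability-recovery and
QTL-recovery experiments run at the full default design
(1,500 / 800 / 3,000, chains of 50,000) over 10 seeds each; the null
calibration of the weighting loop runs 20 seeds at a lighter design
(~450 animals, 1,000 SNPs) chosen to keep the property measurable while
the whole suite stays desk-scale.

## Known limitations

* **Window mapping under linkage equilibrium is weak.** The back-solve is
  a minimum-norm decomposition: with $m$ SNPs and $n_g$ genotyped
  animals it attenuates even a perfectly estimated single-SNP QTL effect
  by roughly $n_g/m$, and the pedigree-driven polygenic part of the GEBVs
  spreads over all markers as noise of comparable window-level size. In
  our no-LD simulations, 4%-of-variance QTL are recovered only
  sporadically, and re-weighting amplifies whichever windows — signal or
  noise — lead after round one. On real panels the signal of a QTL is
  carried redundantly by many markers of its window, which is what makes
  the published applications of this scheme work; conclusions about
  detection power on real data should not be drawn from the LE
  simulations.
* **The weighting loop self-reinforces.** Under a pure-noise GEBV the
  maximum window percentage grows between rounds (the normalisation
  conserves the total, not the maximum). This is inherent to the
  $\hat u^2$ weighting and is why the default stops at two rounds;
  treat window percentages from later rounds as rankings, not calibrated
  fractions.
* **Boundary heritabilities.** The inverse chi-square prior keeps
  $h^2$ posteriors off exact zero; a null trait shows up as an HPD
  hugging (not containing) zero.
* **No LD, no selection** in the generator, as above; and annotation is
  strictly against a user-supplied local GFF3 — no remote databases.
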