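test_that("the backsolve reproduces GEBVs and known regression solutions", {
  # zero GEBVs -> zero effects
  Z0 <- matrix(rnorm(50), 5, 10)
  u0 <- backsolve_snp_effects(rep(0, 5), Z0)
  expect_equal(as.numeric(u0), rep(0, 10))
  expect_equal(attr(u0, "base"), 0)

  # orthogonal columns, D = I: effects equal least-squares coefficients
  Zo <- cbind(c(2, 0, 0, 0), c(0, 0, 3, 0))
  ag <- c(4, 0, 9, 0)
  uo <- backsolve_snp_effects(ag, Zo)
  expect_equal(as.numeric(uo), as.numeric(qr.solve(Zo, ag)), tolerance = 1e-10)

  # full-rank uncentred instance: Z u = a_g to 1e-8, base 0
  set.seed(20)
  Zf <- matrix(rbinom(12 * 40, 2, 0.4), 12, 40)
  af <- rnorm(12)
  d <- runif(40, 0.2, 2)
  uf <- backsolve_snp_effects(af, Zf, d)
  expect_lt(max(abs(Zf %*% as.numeric(uf) - af)), 1e-8)
  expect_equal(attr(uf, "base"), 0)

  # centred instance: rank-one null space along the ones vector; the
  # decomposition recovers every deviation from the group mean exactly
  Zc <- sweep(Zf, 2, colMeans(Zf))
  uc <- backsolve_snp_effects(af, Zc, d)
  expect_equal(attr(uc, "base"), mean(af))
  expect_lt(max(abs(Zc %*% as.numeric(uc) + attr(uc, "base") - af)), 1e-8)

  # an identically zero operator is refused
  expect_error(backsolve_snp_effects(af, matrix(0, 12, 40)), "blended")

  # duplicated animals: minimum-norm solve fits within the attainable range
  Zdup <- Zc; Zdup[2, ] <- Zdup[1, ]
  udup <- backsolve_snp_effects(af, Zdup, d)
  fitted <- as.numeric(Zdup %*% as.numeric(udup)) + attr(udup, "base")
  expect_equal(fitted[1], fitted[2], tolerance = 1e-8)
})

test_that("SNP weights follow u^2 2p(1-p) and normalisation conserves variance", {
  expect_equal(snp_weights(c(0, 1, 0.2), c(0.4, 0.5, 0.3)),
               c(0, 0.5, 0.0168), tolerance = 1e-12)
  expect_error(snp_weights(c(1, 1), c(0, 0.5)), "strictly in")

  p <- c(0.2, 0.5, 0.7)
  # already-normalised weights are a fixed point
  d0 <- normalize_weights(c(2, 0.5, 1), p)
  expect_equal(normalize_weights(d0, p), d0, tolerance = 1e-12)
  # constant weights normalise to all ones
  expect_equal(normalize_weights(rep(3.7, 3), p), rep(1, 3), tolerance = 1e-12)
  # random instance satisfies the constraint to 1e-12
  set.seed(21)
  dr <- normalize_weights(runif(50), pr <- runif(50, 0.1, 0.9))
  expect_equal(sum(dr * 2 * pr * (1 - pr)), sum(2 * pr * (1 - pr)),
               tolerance = 1e-12)
  expect_error(normalize_weights(c(0, 0, 0), p), "zero")
})

test_that("a single weighting round reproduces the unweighted backsolve", {
  cfg <- small_cfg(seed = 101, qtl_spec = data.frame(snp = 500, frac = 0.2))
  b <- sim_bundle(cfg)
  sols <- run_weighted_iterations(b$gi, b$design, b$a_inv, b$a22,
                                  sigma2_a = 0.3, sigma2_e = 0.7, n_iter = 1)
  expect_length(sols, 1L)
  expect_true(all(sols[[1]]$snp$d == 1))

  # identical to assembling the stages by hand with D = I
  p <- allele_freqs(b$gi)
  g_raw <- build_raw_G(b$gi)
  tg <- tune_G(g_raw, b$a22)
  h <- build_H_inverse(b$a_inv, b$a22, blend_G(tg$g_tuned, b$a22), b$gidx)
  s <- mme_solve(b$design$y, b$design$X, b$design$Z, h, 0.3, 0.7)
  Z <- b$gi$calls - matrix(2 * p, nrow(b$gi$calls), ncol(b$gi$calls), byrow = TRUE)
  u <- backsolve_snp_effects(s$a[b$gidx], Z)
  expect_equal(sols[[1]]$snp$u_hat, as.numeric(u), tolerance = 1e-10)
  expect_lt(sols[[1]]$backsolve_residual, 1e-8)
})

test_that("iterating the weights amplifies a planted QTL", {
  cfg <- small_cfg(seed = 101, qtl_spec = data.frame(snp = 500, frac = 0.2))
  b <- sim_bundle(cfg)
  sols <- run_weighted_iterations(b$gi, b$design, b$a_inv, b$a22,
                                  sigma2_a = 0.3, sigma2_e = 0.7, n_iter = 2)
  j <- match("SNP00500", b$gi$map$snp_id)
  expect_false(is.na(j))
  # the QTL's weight increases from the D = I round to the reweighted round
  expect_gt(sols[[2]]$snp$d[j], sols[[1]]$snp$d[j])
  # and again after the second update
  expect_gt(sols[[2]]$snp$d_next[j], sols[[1]]$snp$d_next[j])
  # weight-sum conservation at every round
  for (s in sols) {
    het <- 2 * s$snp$p * (1 - s$snp$p)
    expect_equal(sum(s$snp$d_next * het), sum(het), tolerance = 1e-10)
  }
})

test_that("window variances decompose the marker variance by map blocks", {
  # all-zero effects
  g <- make_geno(matrix(rbinom(200, 2, 0.5), 10, 20))
  Z <- g$calls - matrix(colMeans(g$calls), 10, 20, byrow = TRUE)
  w0 <- window_variances(rep(0, 20), Z, 1, g$map, window_size = 10)
  expect_true(all(w0$pct_variance == 0))
  expect_equal(nrow(w0), 2L)

  # effects confined to one window of independent SNPs
  set.seed(22)
  Zi <- matrix(rnorm(200 * 30), 200, 30)
  u <- c(rnorm(10), rep(0, 20))
  gmap <- make_geno(matrix(0L, 2, 30))$map
  a1 <- as.numeric(Zi[, 1:10] %*% u[1:10])
  wc <- window_variances(u, Zi, sigma2_a = var(a1), gmap, window_size = 10)
  expect_equal(wc$pct_variance[1], 100, tolerance = 1e-10)
  expect_equal(wc$pct_variance[2:3], c(0, 0))

  # 5 animals x 10 SNPs: spreadsheet-style hand computation
  calls <- matrix(c(0,1,2,1,0, 2,2,1,0,1, 1,1,1,2,0, 0,0,1,1,2, 2,1,0,1,1,
                    1,2,1,0,0, 0,1,1,2,2, 2,0,0,1,1, 1,1,2,2,0, 0,2,1,1,1),
                  nrow = 5)
  uh <- seq(0.1, 1.0, by = 0.1)
  Zh <- sweep(calls, 2, colMeans(calls))
  av <- numeric(5)
  for (i in 1:5) { s <- 0; for (j in 1:10) s <- s + Zh[i, j] * uh[j]; av[i] <- s }
  vh <- sum((av - sum(av) / 5)^2) / 4
  gh <- make_geno(calls)
  wh <- window_variances(uh, Zh, sigma2_a = 0.25, gh$map, window_size = 10)
  expect_equal(wh$pct_variance, 100 * vh / 0.25, tolerance = 1e-12)
  expect_equal(wh$n_snps, 10L)

  # trailing remainder becomes a short flagged window
  wr <- window_variances(uh, Zh, 0.25, gh$map, window_size = 7)
  expect_equal(wr$n_snps, c(7L, 3L))
  expect_error(window_variances(uh, Zh, 0.25, gh$map, window_size = 0), "window_size")
  expect_error(window_variances(uh, Zh, 0, gh$map), "sigma2_a")
})

test_that("window percentages are invariant to SNP storage order", {
  cfg <- small_cfg(seed = 111, n_chromosomes = 3, snps_per_chromosome = 60)
  b <- sim_bundle(cfg)
  p <- allele_freqs(b$gi)
  Z <- b$gi$calls - matrix(2 * p, nrow(b$gi$calls), ncol(b$gi$calls), byrow = TRUE)
  u <- withr::with_seed(23, rnorm(ncol(Z), sd = 0.05))
  w1 <- window_variances(u, Z, 0.3, b$gi$map)

  # jointly permute columns and map rows, then restore map order
  m <- ncol(Z)
  perm <- withr::with_seed(24, sample.int(m))
  map_p <- b$gi$map[perm, ]
  ord <- order(match(map_p$chrom, unique(b$gi$map$chrom)), map_p$pos_bp)
  w2 <- window_variances(u[perm][ord], Z[, perm][, ord], 0.3, map_p[ord, ])
  expect_equal(w2$pct_variance, w1$pct_variance, tolerance = 1e-12)
  expect_equal(w2$start_snp, w1$start_snp)
})

test_that("region selection applies the threshold with deterministic ordering", {
  rep_tb <- tibble::tibble(
    window = 1:3, chrom = c("1", "2", "3"),
    start_snp = c("a", "b", "c"), end_snp = c("a2", "b2", "c2"),
    start_bp = c(100L, 200L, 300L), end_bp = c(900L, 950L, 990L),
    n_snps = 10L, pct_variance = c(1.29, 6.64, 0.9))
  class(rep_tb) <- c("window_report", class(rep_tb))
  sel <- select_regions(rep_tb)
  expect_equal(sel$pct_variance, c(6.64, 1.29))
  expect_equal(nrow(select_regions(rep_tb, threshold_pct = 10)), 0L)
  expect_equal(nrow(select_regions(rep_tb, threshold_pct = 0)), 3L)
  # ties order by chromosome then position
  tie <- rep_tb; tie$pct_variance <- c(2, 2, 2)
  expect_equal(select_regions(tie)$chrom, c("1", "2", "3"))
})
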