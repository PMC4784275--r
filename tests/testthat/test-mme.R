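test_that("design matrices have the documented structure", {
  ped <- tibble::tibble(animal = 1:5, sire = 0L, dam = 0L)
  phen <- tibble::tibble(animal_id = 1:5,
                         trait_value = c(1, 2, 3, 2.5, 1.5),
                         cg = factor(c("g1", "g1", "g2", "g2", "g1")),
                         age = c(600L, 650L, 700L, 620L, 680L))
  d <- build_design_matrices(phen, ped)
  # 2 CGs: intercept + 1 CG indicator (reference absorbed) + 2 age columns
  expect_equal(ncol(d$X), 4L)
  expect_equal(sum(grepl("^cg", colnames(d$X))), 1L)
  expect_true(all(c("age", "age2") %in% colnames(d$X)))
  expect_equal(dim(d$Z), c(5L, 5L))
  expect_equal(d$rec_animal, 1:5)

  # equal ages: degenerate covariates dropped with a message
  phen_const <- phen; phen_const$age <- 700L
  expect_message(d2 <- build_design_matrices(phen_const, ped), "degenerate")
  expect_equal(ncol(d2$X), 2L)

  # permuting records permutes y, X, Z rows consistently
  prm <- c(3L, 1L, 5L, 2L, 4L)
  d3 <- build_design_matrices(phen[prm, ], ped)
  expect_equal(d3$y, d$y[prm])
  expect_equal(unname(d3$X), unname(d$X[prm, ]))
  expect_equal(as.matrix(d3$Z), as.matrix(d$Z)[prm, ])

  expect_error(build_design_matrices(dplyr::mutate(phen, animal_id = c(1L, 2L, 9L, 4L, 5L)), ped),
               "absent from pedigree")
})

test_that("the direct solver obeys its shrinkage and equivalence limits", {
  cfg <- sim_config(n_founders = 30, n_generations = 2, n_matings = 20,
                    offspring_per_mating = 2, n_chromosomes = 1,
                    snps_per_chromosome = 50, prop_genotyped = 0.4,
                    h2 = 0.4, seed = 71)
  b <- sim_bundle(cfg)
  a_tab <- build_A_tabular(b$ped)

  # enormous lambda: a -> 0, beta -> OLS
  s_inf <- mme_solve(b$design$y, b$design$X, b$design$Z, b$a_inv,
                     sigma2_a = 1e-12, sigma2_e = 1)
  expect_lt(max(abs(s_inf$a)), 1e-6)
  ols <- qr.solve(b$design$X, b$design$y)
  expect_equal(unname(s_inf$beta), unname(ols), tolerance = 1e-6)

  # pedigree-only: identical to a BLUP assembled from the generic inverse
  # of the tabular A (independent route to the same model)
  s_ped <- mme_solve(b$design$y, b$design$X, b$design$Z, b$a_inv, 0.4, 0.6)
  lam <- 0.6 / 0.4
  X <- b$design$X; Z <- as.matrix(b$design$Z); y <- b$design$y
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lam * solve(a_tab)))
  sol <- solve(C, c(crossprod(X, y), crossprod(Z, y)))
  expect_equal(unname(s_ped$beta), unname(sol[seq_len(ncol(X))]), tolerance = 1e-8)
  expect_equal(unname(s_ped$a), unname(sol[-seq_len(ncol(X))]), tolerance = 1e-8)

  # shifting y moves the intercept only; breeding values unchanged
  s_shift <- mme_solve(y + 10, X, b$design$Z, b$a_inv, 0.4, 0.6)
  expect_equal(unname(s_shift$a), unname(s_ped$a), tolerance = 1e-8)
  expect_equal(unname(s_shift$beta["(Intercept)"] - s_ped$beta["(Intercept)"]),
               10, tolerance = 1e-8)

  expect_error(mme_solve(y, X, b$design$Z, b$a_inv, 0, 1), "positive")
})

test_that("the direct solver matches a GLS oracle on a tiny instance", {
  # 4 animals: two founders, an offspring, and a grand-offspring
  ped <- tibble::tibble(animal = 1:4, sire = c(0L, 0L, 1L, 1L),
                        dam = c(0L, 0L, 2L, 3L))
  A <- build_A_tabular(ped)
  y <- c(2.1, 0.7, 1.4, 2.9)
  X <- matrix(1, 4, 1)
  Z <- Matrix::sparseMatrix(i = 1:4, j = 1:4, x = 1)
  s <- mme_solve(y, X, Z, build_A_inverse(ped), sigma2_a = 0.5, sigma2_e = 1.5)

  # GLS route: V = Z A Z' s2a + I s2e; beta = (X'V^-1X)^-1 X'V^-1 y;
  # a = s2a A Z' V^-1 (y - X beta)
  V <- A * 0.5 + diag(4) * 1.5
  Vi <- solve(V)
  beta_gls <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  a_gls <- 0.5 * A %*% Vi %*% (y - X %*% beta_gls)
  expect_equal(unname(s$beta), as.numeric(beta_gls), tolerance = 1e-10)
  expect_equal(unname(s$a), as.numeric(a_gls), tolerance = 1e-10)
})

test_that("Gibbs sampling is deterministic and matches the solver at fixed variances", {
  cfg <- sim_config(n_founders = 40, n_generations = 2, n_matings = 30,
                    offspring_per_mating = 2, n_chromosomes = 1,
                    snps_per_chromosome = 120, prop_genotyped = 0.5,
                    h2 = 0.4, seed = 83)
  b <- sim_bundle(cfg)
  g_raw <- build_raw_G(b$gi)
  tg <- tune_G(g_raw, b$a22)
  h <- build_H_inverse(b$a_inv, b$a22, blend_G(tg$g_tuned, b$a22), b$gidx)

  ch <- list(length = 6000L, burn_in = 1000L, thin = 2L, seed = 99L)
  f1 <- gibbs_fit(b$design$y, b$design$X, b$design$Z, h, chain = ch)
  f2 <- gibbs_fit(b$design$y, b$design$X, b$design$Z, h, chain = ch)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$ebv, f2$ebv)
  expect_true(all(f1$chains$sigma2_a > 0 & f1$chains$sigma2_e > 0))
  expect_true(all(f1$chains$h2 > 0 & f1$chains$h2 < 1))
  expect_equal(nrow(f1$ebv), nrow(b$ped))

  # fixed variances: posterior means converge to the exact MME solutions
  chf <- list(length = 20000L, burn_in = 2000L, thin = 2L, seed = 7L)
  ff <- gibbs_fit(b$design$y, b$design$X, b$design$Z, h, chain = chf,
                  fix_variances = TRUE,
                  start = list(sigma2_a = 0.4, sigma2_e = 0.6))
  s <- mme_solve(b$design$y, b$design$X, b$design$Z, h, 0.4, 0.6)
  expect_true(all(ff$chains$sigma2_a == 0.4))
  expect_gt(cor(ff$ebv$gebv, s$a), 0.999)
  expect_lt(max(abs(ff$ebv$gebv - s$a)), 0.05)

  # rescaling y leaves the h2 chain unchanged and scales variances by 4
  fy <- gibbs_fit(2 * b$design$y, b$design$X, b$design$Z, h, chain = ch)
  expect_equal(fy$chains$h2, f1$chains$h2, tolerance = 1e-12)
  expect_equal(fy$chains$sigma2_a, 4 * f1$chains$sigma2_a, tolerance = 1e-10)

  expect_error(gibbs_fit(b$design$y, b$design$X, b$design$Z, h,
                         chain = list(length = 100L, burn_in = 200L)),
               "burn_in")
})

test_that("a heritability of zero concentrates the posterior at the boundary", {
  cfg <- sim_config(n_founders = 150, n_generations = 2, n_matings = 100,
                    offspring_per_mating = 3, n_chromosomes = 1,
                    snps_per_chromosome = 150, prop_genotyped = 0.4,
                    h2 = 0, seed = 91)
  b <- sim_bundle(cfg)
  g_raw <- build_raw_G(b$gi)
  tg <- tune_G(g_raw, b$a22)
  h <- build_H_inverse(b$a_inv, b$a22, blend_G(tg$g_tuned, b$a22), b$gidx)
  fit <- gibbs_fit(b$design$y, b$design$X, b$design$Z, h,
                   chain = list(length = 20000L, burn_in = 2000L,
                                thin = 5L, seed = 5L))
  s <- posterior_summary(fit$chains$h2)
  # the scaled-inverse-chi-square prior (df 4, ANOVA-split scale) carries
  # essentially no mass at sigma2_a = 0, so the posterior concentrates just
  # above the boundary rather than on it
  expect_lt(s$hpd_low, 0.06)
  expect_lt(s$median, 0.1)
  expect_lt(s$mean, 0.12)
})
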