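test_that("A inverse matches known closed forms", {
  founders <- tibble::tibble(animal = 1:3, sire = 0L, dam = 0L)
  expect_equal(as.matrix(build_A_inverse(founders)), diag(3),
               ignore_attr = TRUE, tolerance = 1e-14)

  # non-inbred trio: invert the 3x3 tabular A by hand
  expect_equal(as.matrix(build_A_inverse(trio_ped())),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3),
               ignore_attr = TRUE, tolerance = 1e-12)

  # cyclic / unordered pedigree refused with the offending animal named
  bad <- tibble::tibble(animal = 1:2, sire = c(2L, 0L), dam = c(0L, 0L))
  expect_error(build_A_inverse(bad), "animal '1'")
  expect_error(build_A_inverse(tibble::tibble(animal = 1:3,
                                              sire = c(0L, 0L, 1L),
                                              dam = c(0L, 0L, 1L))),
               "sire equals dam")
})

test_that("recursive A inverse inverts the tabular A on inbred pedigrees", {
  # deep pedigree with few parents per generation -> inbreeding accumulates
  cfg <- sim_config(n_founders = 20, n_generations = 5, n_matings = 18,
                    offspring_per_mating = 2, seed = 13)
  ped <- simulate_pedigree(cfg) # 200 animals
  A <- build_A_tabular(ped)
  Ainv <- as.matrix(build_A_inverse(ped))
  expect_lt(max(abs(Ainv %*% A - diag(nrow(A)))), 1e-8)
  # positive semidefinite, diagonal = 1 + F >= 1
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_true(all(diag(A) >= 1 - 1e-12))
  expect_gt(max(diag(A)), 1) # inbreeding did occur
  # inbreeding from the recursion agrees with the tabular diagonal
  expect_equal(unname(inbreeding(ped)), unname(diag(A) - 1), tolerance = 1e-10)
})

test_that("A22 is the genotyped submatrix of the tabular A", {
  cfg <- sim_config(n_founders = 25, n_generations = 3, n_matings = 15,
                    offspring_per_mating = 2, seed = 17)
  ped <- simulate_pedigree(cfg)
  A <- build_A_tabular(ped)
  ids <- as.character(ped$animal)
  sub <- withr::with_seed(2, sample(ids, 40))
  expect_equal(build_A22(ped, sub), A[sub, sub], tolerance = 1e-12)
  expect_equal(build_A22(ped, ids), A, tolerance = 1e-12)
  founders <- ids[ped$sire == 0 & ped$dam == 0]
  expect_equal(build_A22(ped, founders), diag(length(founders)),
               ignore_attr = TRUE, tolerance = 1e-14)
  expect_error(build_A22(ped, "nope"), "absent from pedigree")
})

test_that("raw G equals the hand-computed Z D Z' over the base factor", {
  calls <- rbind(A1 = c(0L, 1L, 2L, 1L),
                 A2 = c(1L, 1L, 0L, 2L),
                 A3 = c(2L, 0L, 1L, 1L))
  g <- make_geno(calls)
  d <- c(1, 0.5, 2, 1)
  G <- build_raw_G(g, weights = d)

  # independent arithmetic: explicit loops over animals and SNPs
  p <- colSums(calls) / (2 * nrow(calls))
  base <- sum(2 * p * (1 - p))
  Gexp <- matrix(0, 3, 3)
  for (i in 1:3) for (k in 1:3) {
    s <- 0
    for (j in 1:4)
      s <- s + d[j] * (calls[i, j] - 2 * p[j]) * (calls[k, j] - 2 * p[j])
    Gexp[i, k] <- s / base
  }
  expect_equal(unname(G), Gexp, tolerance = 1e-12)

  # identical genotypes give identical rows/columns
  g2 <- make_geno(rbind(calls, A4 = calls[1, ]))
  G2 <- build_raw_G(g2)
  expect_equal(G2[1, ], G2[4, ], tolerance = 1e-12)
  expect_equal(G2[, 1], G2[, 4], tolerance = 1e-12)

  # linearity in D
  expect_equal(build_raw_G(g, weights = 2 * d), 2 * G, tolerance = 1e-12)

  # monomorphic columns are refused
  gm <- make_geno(cbind(calls, A5 = c(2L, 2L, 2L)))
  expect_error(build_raw_G(gm), "monomorphic")
  gna <- make_geno(calls); gna$calls[1, 1] <- NA
  expect_error(build_raw_G(gna), "impute")
})

test_that("tuning matches mean diagonals exactly and blending fixes rank", {
  g0 <- diag(c(0.9, 1.1, 1.0))
  expect_equal(tune_G(g0, g0)$q, 1, tolerance = 1e-14)
  expect_equal(tune_G(0.5 * diag(3), diag(3))$q, 2, tolerance = 1e-14)

  set.seed(4)
  M <- crossprod(matrix(rnorm(36), 6))
  A22 <- diag(6) + 0.1
  tg <- tune_G(M, A22)
  expect_equal(mean(diag(tg$g_tuned)), mean(diag(A22)), tolerance = 1e-12)

  expect_equal(blend_G(tg$g_tuned, A22, 0), tg$g_tuned, tolerance = 1e-14)
  expect_equal(blend_G(tg$g_tuned, A22, 1), A22, tolerance = 1e-14)

  # duplicated-animal G is singular; 5% pedigree admixture restores rank
  Zdup <- matrix(rnorm(40), 4, 10)
  Zdup[4, ] <- Zdup[1, ]
  Gdup <- tcrossprod(Zdup) / 10
  A22d <- diag(4); A22d[1, 4] <- A22d[4, 1] <- 0.5
  expect_lt(min(eigen(Gdup, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
  gb <- blend_G(Gdup, A22d, 0.05)
  expect_gt(min(eigen(gb, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("H inverse reduces to its algebraic limits", {
  cfg <- sim_config(n_founders = 15, n_generations = 2, n_matings = 10,
                    offspring_per_mating = 2, seed = 23)
  ped <- simulate_pedigree(cfg)
  a_inv <- build_A_inverse(ped)
  n <- nrow(ped)
  ids <- as.character(ped$animal)

  # empty genotyped set: H^-1 = A^-1 exactly
  h0 <- build_H_inverse(a_inv, matrix(0, 0, 0), matrix(0, 0, 0), integer(0))
  expect_equal(as.matrix(h0), as.matrix(a_inv), tolerance = 1e-15)

  # g_final = a22: correction vanishes
  gids <- ids[21:45]
  a22 <- build_A22(ped, gids)
  hsame <- build_H_inverse(a_inv, a22, a22, gids)
  expect_equal(as.matrix(hsame), as.matrix(a_inv), tolerance = 1e-10)

  # all animals genotyped with some G: H^-1 = G^-1
  A <- build_A_tabular(ped)
  set.seed(6)
  Gfull <- A + crossprod(matrix(rnorm(n * n, sd = 0.05), n))
  hfull <- build_H_inverse(a_inv, A, Gfull, ids)
  expect_equal(as.matrix(hfull), solve(Gfull), tolerance = 1e-6)

  expect_error(build_H_inverse(a_inv, a22, a22[1:3, 1:3], gids), "mismatch")
})

test_that("H inverse construction commutes with animal relabeling", {
  cfg <- sim_config(n_founders = 12, n_generations = 2, n_matings = 8,
                    offspring_per_mating = 2, seed = 29)
  ped <- simulate_pedigree(cfg)
  ids <- as.character(ped$animal)
  gids <- ids[c(15, 3, 28, 20, 9, 40, 33)]
  a22 <- build_A22(ped, gids)
  g <- blend_G(a22 + diag(0.1, length(gids)), a22, 0.05)
  h1 <- as.matrix(build_H_inverse(build_A_inverse(ped), a22, g, gids))

  # relabel: permute founder block (still topologically ordered)
  perm <- withr::with_seed(8,
    c(sample(which(ped$generation == 0)), which(ped$generation > 0)))
  ped2 <- ped[perm, ]
  h2 <- as.matrix(build_H_inverse(build_A_inverse(ped2), a22, g, gids))
  ids2 <- as.character(ped2$animal)
  expect_equal(h2[match(ids, ids2), match(ids, ids2)], h1,
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("genomic and pedigree relationships agree on average after gene dropping", {
  cfg <- small_cfg(seed = 61, missing_rate = 0)
  b <- sim_bundle(cfg)
  # centre at the founder (base-population) frequencies, under which the
  # genomic relationships are unbiased for the pedigree expectations
  tr <- attr(b$geno, "truth")
  p0 <- tr$founder_freq[match(b$gi$map$snp_id,
                              sprintf("SNP%05d", seq_along(tr$founder_freq)))]
  G <- build_raw_G(b$gi, p = p0)
  off_g <- mean(G[upper.tri(G)])
  off_a <- mean(b$a22[upper.tri(b$a22)])
  expect_lt(abs(off_g - off_a), 0.02)
  expect_lt(abs(mean(diag(G)) - mean(diag(b$a22))), 0.05)
})
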