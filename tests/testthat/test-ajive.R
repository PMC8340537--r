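test_that("truncated block SVD returns factors and the noise threshold", {
  basis <- randBasis(20, 2, seed = 40)
  b <- plantedBlock(30, basis, seed = 41)
  sv <- truncatedBlockSVD(b, 2)
  approx <- sv@leftBasis %*% (sv@singularValues * t(sv@rowBasis))
  expect_equal(unname(approx), unname(blockValues(b)), tolerance = 1e-10)
  expect_lt(sv@noiseThreshold, 1e-10)
  expect_equal(crossprod(sv@rowBasis), diag(2), tolerance = 1e-12)

  # constructed 3x3 with singular values (5, 3, 1): threshold after r=1 is 3
  U <- randBasis(3, 3, seed = 42, center = FALSE)
  V <- randBasis(3, 3, seed = 43, center = FALSE)
  m <- U %*% diag(c(5, 3, 1)) %*% t(V)
  dimnames(m) <- list(paste0("f", 1:3), paste0("s", 1:3))
  sv1 <- truncatedBlockSVD(OmicsBlock(m, "d", "expression_log"), 1)
  expect_equal(sv1@noiseThreshold, 3, tolerance = 1e-10)
  expect_equal(sv1@discarded, c(3, 1), tolerance = 1e-10)

  expect_error(truncatedBlockSVD(b, 0), "out of range")
  expect_error(truncatedBlockSVD(b, 20), "out of range")
})

test_that("stacked-basis spectrum encodes principal angles", {
  n <- 12
  e1 <- diag(n)[, 1, drop = FALSE]
  e2 <- diag(n)[, 2, drop = FALSE]
  mk <- function(V) new("BlockSVD", name = "b", rank = 1L,
                        leftBasis = matrix(1), singularValues = 1,
                        rowBasis = V, noiseThreshold = 0,
                        discarded = numeric(0))
  # identical rank-1 bases: perfectly shared direction attains K = 2
  out <- stackedBasisSVD(list(mk(e1), mk(e1)))
  expect_equal(out$squaredSingularValues[1], 2, tolerance = 1e-12)
  # orthogonal bases: both squared singular values equal 1
  out90 <- stackedBasisSVD(list(mk(e1), mk(e2)))
  expect_equal(out90$squaredSingularValues, c(1, 1), tolerance = 1e-12)
  # bases at angle theta: the 2x2 Gram matrix of the stacked frame has
  # eigenvalues 1 +/- cos(theta), so at 60 degrees the top squared singular
  # value is 1 + cos(60) = 1.5
  v60 <- cos(pi / 3) * e1 + sin(pi / 3) * e2
  out60 <- stackedBasisSVD(list(mk(e1), mk(v60)))
  expect_equal(out60$squaredSingularValues[1], 1.5, tolerance = 1e-12)
  expect_equal(out60$squaredSingularValues[2], 0.5, tolerance = 1e-12)
  expect_error(stackedBasisSVD(list(mk(e1))), "at least 2")
})

test_that("wedin bound is K for noiseless blocks and drops with pure noise", {
  basis <- randBasis(25, 2, seed = 50)
  svds <- list(truncatedBlockSVD(plantedBlock(40, basis, seed = 51), 2),
               truncatedBlockSVD(plantedBlock(30, basis, seed = 52,
                                              name = "p2"), 2))
  expect_equal(wedinBound(svds, 50, seed = 1), 2, tolerance = 1e-8)

  noisy <- list(svds[[1]],
                truncatedBlockSVD(centerFeatures(toyBlock(30, 25, seed = 53)),
                                  2))
  tNoisy <- wedinBound(noisy, 200, seed = 2)
  expect_lt(tNoisy, 1.7)
  expect_identical(wedinBound(noisy, 200, seed = 2),
                   wedinBound(noisy, 200, seed = 2))
  expect_error(wedinBound(svds, 1, seed = 1), "n_resample")
})

test_that("random-direction bound reflects dimension and is deterministic", {
  tBig <- randomDirectionBound(c(1, 1), n = 2000, n_draws = 50, seed = 3)
  expect_lt(abs(tBig - 1), 0.1)
  tSmall <- randomDirectionBound(c(4, 4), n = 5, n_draws = 50, seed = 4)
  expect_gt(tSmall, 1.8)
  expect_identical(randomDirectionBound(c(2, 2), 30, 100, seed = 5),
                   randomDirectionBound(c(2, 2), 30, 100, seed = 5))
  expect_error(randomDirectionBound(c(5, 2), n = 5), "smaller than n")
})

test_that("joint-rank selection counts exceedances with the noiseless escape", {
  expect_identical(selectJointRank(c(1.9, 1.2, 0.4), 1.5, 1.1), 1L)
  expect_identical(selectJointRank(c(0.9, 0.5), 1.5, 1.1), 0L)
  # noiseless tie: squared values of exactly K retained when t_wedin = K
  expect_identical(selectJointRank(c(2, 2, 1), 2, 1.2, ranks = c(2, 2)), 2L)
  # cap at the smallest block rank
  expect_identical(selectJointRank(c(1.9, 1.8, 1.7), 1.0, 1.0,
                                   ranks = c(1, 5)), 1L)
})

test_that("joint extraction is an exact row-space projection", {
  basis <- randBasis(20, 3, seed = 60)
  b1 <- plantedBlock(35, basis, seed = 61)
  b2 <- plantedBlock(25, basis, seed = 62, name = "p2")
  out <- extractJoint(list(b1, b2), basis)
  expect_equal(out$J[[1]], blockValues(b1), tolerance = 1e-10)

  # r_J = 0: all joint components vanish
  out0 <- extractJoint(list(b1, b2), matrix(0, 20, 0))
  expect_true(all(out0$J[[1]] == 0))

  # oracle: projection residual equals per-row least squares on the basis
  X <- blockValues(centerFeatures(toyBlock(10, 20, seed = 63)))
  V <- randBasis(20, 2, seed = 64)
  J <- extractJoint(list(OmicsBlock(X, "x", "expression_log")), V)$J[[1]]
  for (i in 1:5) {
    fitted <- V %*% qr.solve(V, X[i, ])
    expect_equal(unname(J[i, ]), as.numeric(fitted), tolerance = 1e-8)
  }
})

test_that("individual extraction thresholds the remainder spectrum", {
  basis <- randBasis(24, 2, seed = 70)
  # block entirely within the joint span: individual vanishes
  b <- plantedBlock(30, basis, seed = 71)
  J <- extractJoint(list(b), basis)$J[[1]]
  res <- extractIndividual(b, J, noise_threshold = 0, V_J = basis)
  expect_identical(res$rank, 0L)
  expect_lt(max(abs(res$I)), 1e-8)

  # noiseless remainder of rank 3 at threshold 0
  iBasis <- randBasis(24, 3, seed = 72)
  iBasis <- qr.Q(qr(iBasis - basis %*% crossprod(basis, iBasis)))[, 1:3]
  b2 <- plantedBlock(30, iBasis, seed = 73, name = "ind")
  res2 <- extractIndividual(b2, matrix(0, 30, 24), 0, V_J = basis)
  expect_identical(res2$rank, 3L)
  expect_lt(max(abs(res2$E)), 1e-8)

  # constructed remainder with singular values (5, 2, 0.5), threshold 1
  U <- randBasis(30, 3, seed = 74, center = FALSE)
  V <- randBasis(24, 3, seed = 75)
  R <- U %*% diag(c(5, 2, 0.5)) %*% t(V)
  dimnames(R) <- list(paste0("f", 1:30), paste0("s", 1:24))
  res3 <- extractIndividual(OmicsBlock(R, "r", "expression_log"),
                            matrix(0, 30, 24), 1)
  expect_identical(res3$rank, 2L)
})

test_that("fully shared noiseless blocks yield joint-only decompositions", {
  basis <- randBasis(30, 2, seed = 80)
  coll <- twoBlockCollection(plantedBlock(40, basis, seed = 81, name = "b1"),
                             plantedBlock(35, basis, seed = 82, name = "b2"))
  fit <- ajive(coll, c(b1 = 2, b2 = 2), n_resample = 50, n_draws = 50,
               seed = 1)
  expect_identical(jointRank(fit), 2L)
  expect_identical(unname(individualRanks(fit)), c(0L, 0L))
  for (k in 1:2) expect_lt(max(abs(fit@E[[k]])), 1e-8)
  expect_equal(unname(varianceExplained(fit)[, "joint"]), c(1, 1),
               tolerance = 1e-8)
  # acos loses precision near 1, so tiny true angles read as ~1e-8
  expect_lt(maxPrincipalAngle(jointScores(fit), basis), 1e-6)
})

test_that("orthogonal planted row spaces give no joint structure", {
  A <- randBasis(40, 2, seed = 83)
  Braw <- randBasis(40, 3, seed = 84)
  B <- qr.Q(qr(Braw - A %*% crossprod(A, Braw)))[, 1:3]
  coll <- twoBlockCollection(plantedBlock(30, A, seed = 85, name = "b1"),
                             plantedBlock(30, B, seed = 86, name = "b2"))
  fit <- ajive(coll, c(b1 = 2, b2 = 3), n_resample = 50, n_draws = 50,
               seed = 2)
  expect_identical(jointRank(fit), 0L)
  expect_identical(unname(individualRanks(fit)), c(2L, 3L))
  expect_equal(unname(varianceExplained(fit)[, "individual"]), c(1, 1),
               tolerance = 1e-8)
})

test_that("a single block is rejected", {
  b <- plantedBlock(20, randBasis(15, 1, seed = 87))
  expect_error(ajive(MultiOmicsCollection(list(b)), c(planted = 1)),
               "single block")
})

test_that("reconstruction, orthogonality and rank bounds hold on random inputs", {
  set.seed(90)
  for (i in 1:8) {
    n <- sample(15:30, 1)
    K <- sample(2:3, 1)
    bl <- lapply(seq_len(K), function(k)
      centerFeatures(toyBlock(sample(20:50, 1), n, seed = 900 + 10 * i + k,
                              name = paste0("b", k))))
    ranks <- sample(2:4, K, replace = TRUE)
    names(ranks) <- paste0("b", seq_len(K))
    fit <- ajive(MultiOmicsCollection(bl), ranks, n_resample = 50,
                 n_draws = 50, seed = i)
    VJ <- jointScores(fit)
    if (ncol(VJ))
      expect_equal(crossprod(VJ), diag(ncol(VJ)), tolerance = 1e-10)
    expect_lte(jointRank(fit), min(ranks))
    for (k in seq_len(K)) {
      X <- blockValues(bl[[k]])
      recon <- fit@J[[k]] + fit@I[[k]] + fit@E[[k]]
      expect_lt(norm(recon - X, "F") / norm(X, "F"), 1e-8)
      if (ncol(VJ) && any(fit@I[[k]] != 0))
        expect_lt(norm(fit@I[[k]] %*% VJ, "F") / norm(fit@I[[k]], "F"), 1e-8)
      expect_lte(individualRanks(fit)[k], ranks[k])
      expect_lte(qr(fit@J[[k]])$rank, jointRank(fit))
    }
    expect_equal(unname(rowSums(varianceExplained(fit))), rep(1, K),
                 tolerance = 1e-10)
  }
})

test_that("the decomposition is insensitive to block-scale heterogeneity", {
  basis <- randBasis(30, 2, seed = 95)
  b1 <- plantedBlock(40, basis, seed = 96, name = "b1", noise_sd = 0.05)
  b2 <- plantedBlock(35, basis, seed = 97, name = "b2", noise_sd = 0.05)
  base <- ajive(twoBlockCollection(centerFeatures(b1), centerFeatures(b2)),
                c(b1 = 2, b2 = 2), n_resample = 50, n_draws = 50, seed = 7)
  for (c in c(1e-3, 1e3)) {
    scaled <- OmicsBlock(c * blockValues(b1), "b1", "expression_log")
    fit <- ajive(twoBlockCollection(centerFeatures(scaled),
                                    centerFeatures(b2)),
                 c(b1 = 2, b2 = 2), n_resample = 50, n_draws = 50, seed = 7)
    expect_identical(jointRank(fit), jointRank(base))
    expect_lt(maxPrincipalAngle(jointScores(fit), jointScores(base)), 1e-6)
  }
})

test_that("sample permutation permutes scores; block order leaves the span", {
  basis <- randBasis(24, 2, seed = 98)
  b1 <- centerFeatures(plantedBlock(30, basis, seed = 99, name = "b1",
                                    noise_sd = 0.05))
  b2 <- centerFeatures(plantedBlock(25, basis, seed = 100, name = "b2",
                                    noise_sd = 0.05))
  fit <- ajive(twoBlockCollection(b1, b2), c(b1 = 2, b2 = 2),
               n_resample = 50, n_draws = 50, seed = 8)
  perm <- sample(24)
  pb <- function(b) OmicsBlock(blockValues(b)[, perm], blockName(b),
                               "expression_log")
  fitP <- ajive(twoBlockCollection(pb(b1), pb(b2)), c(b1 = 2, b2 = 2),
                n_resample = 50, n_draws = 50, seed = 8)
  expect_lt(maxPrincipalAngle(fitP@joint@rowBasis,
                              fit@joint@rowBasis[perm, , drop = FALSE]),
            1e-6)
  fitSwap <- ajive(MultiOmicsCollection(list(b2, b1)), c(b2 = 2, b1 = 2),
                   n_resample = 50, n_draws = 50, seed = 8)
  expect_lt(maxPrincipalAngle(jointScores(fitSwap), jointScores(fit)), 1e-6)
})

test_that("variance proportions match constructed Frobenius splits", {
  VJ <- randBasis(20, 1, seed = 101)
  VIraw <- randBasis(20, 1, seed = 102)
  VI <- qr.Q(qr(VIraw - VJ %*% crossprod(VJ, VIraw)))[, 1, drop = FALSE]
  set.seed(103)
  lj <- rnorm(30); li <- rnorm(30)
  # scale so the joint part carries 60% of the squared Frobenius norm
  lj <- lj * sqrt(0.6) / sqrt(sum(lj^2))
  li <- li * sqrt(0.4) / sqrt(sum(li^2))
  X <- lj %o% as.numeric(VJ) + li %o% as.numeric(VI)
  dimnames(X) <- list(paste0("f", 1:30), paste0("s", 1:20))
  b <- OmicsBlock(X, "mix", "expression_log")
  J <- extractJoint(list(b), VJ)$J[[1]]
  res <- extractIndividual(b, J, 0, V_J = VJ)
  tot <- sum(X^2)
  expect_equal(sum(J^2) / tot, 0.6, tolerance = 0.02)
  expect_equal(sum(res$I^2) / tot, 0.4, tolerance = 0.02)
})

test_that("synthetic recovery: joint rank and basis are found at snr 5", {
  cfg <- syntheticConfig(n_samples = 60, block_dims = c(300, 150, 60),
                         joint_rank = 2, individual_ranks = c(3, 2, 2),
                         block_scales = c(10, 1, 0.1), snr = c(5, 5, 5),
                         seed = 77)
  sim <- generateBlocks(cfg)
  coll <- centerCollection(sim$collection)
  fit <- ajive(coll, selectInitialRanks(coll), n_resample = 100,
               n_draws = 100, seed = 77)
  expect_identical(jointRank(fit), 2L)
  ang <- maxPrincipalAngle(jointScores(fit), sim$truth@jointScoreBasis)
  expect_lt(ang * 180 / pi, 15)
})
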