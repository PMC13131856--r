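test_that("linear CKA satisfies its identities and invariances", {
  set.seed(1)
  X <- matrix(rnorm(200 * 6), 200, 6)
  expect_equal(linearCKA(X, X), 1, tolerance = 1e-10)

  # orthogonal rotation + translation + positive scaling leave CKA at 1
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  shift <- matrix(rnorm(6), 200, 6, byrow = TRUE)
  expect_equal(linearCKA(X, 3.7 * (X %*% Q) + shift), 1, tolerance = 1e-8)

  # symmetry
  Y <- matrix(rnorm(200 * 4), 200, 4)
  expect_equal(linearCKA(X, Y), linearCKA(Y, X), tolerance = 1e-12)
  expect_gte(linearCKA(X, Y), 0)
  expect_lte(linearCKA(X, Y), 1)

  expect_error(linearCKA(matrix(1, 10, 3), X[1:10, ]), "zero-variance")
})

test_that("independent high-dimensional matrices have near-zero CKA", {
  for (s in 1:20) {
    set.seed(100 + s)
    X <- matrix(rnorm(2000 * 64), 2000, 64)
    Y <- matrix(rnorm(2000 * 64), 2000, 64)
    expect_lt(linearCKA(X, Y), 0.05)
  }
})

test_that("bootstrap CKA separates matched from permuted pairs", {
  set.seed(2)
  A <- matrix(rnorm(60 * 5), 60, 5)
  mkU <- function(m, mod) new("UdipMatrix",
                              subjectIds = sprintf("S%02d", seq_len(nrow(m))),
                              udip = m,
                              explainedVariance = rep(0.1, ncol(m)),
                              qcMask = matrix(TRUE, nrow(m), ncol(m)),
                              modality = mod)
  # identical matrices: every positive-pair CKA is exactly 1
  bs <- ckaBootstrap(mkU(A, "a"), mkU(A, "b"), nBoot = 20L, seed = 4L)
  expect_true(all(abs(bs$pos - 1) < 1e-10))

  # determinism
  bs2 <- ckaBootstrap(mkU(A, "a"), mkU(A, "b"), nBoot = 20L, seed = 4L)
  expect_identical(bs$pos, bs2$pos)
  expect_identical(bs$neg, bs2$neg)

  # independent modality-b: both null distributions sit near zero and far
  # below any real alignment signal (the bootstrap null runs slightly above
  # the permutation null because resampling duplicates rows)
  set.seed(9)
  A2 <- matrix(rnorm(300 * 5), 300, 5)
  B2 <- matrix(rnorm(300 * 5), 300, 5)
  bsN <- ckaBootstrap(mkU(A2, "a"), mkU(B2, "b"), nBoot = 100L, seed = 5L)
  expect_lt(mean(bsN$pos), 0.1)
  expect_lt(mean(bsN$neg), 0.1)
  expect_lt(abs(mean(bsN$pos) - mean(bsN$neg)), 0.05)

  expect_error(ckaBootstrap(A2[1:2, ], B2[1:2, ]), "at least 3")
})

test_that("CCA matches the generalized-eigenproblem oracle", {
  set.seed(6)
  n <- 200L
  X <- matrix(rnorm(n * 5), n, 5)
  Y <- matrix(rnorm(n * 4), n, 4)
  fit <- ccaFit(X, Y)
  expect_length(fit$rho, 4L)

  # oracle: rho^2 are eigenvalues of Syy^-1 Syx Sxx^-1 Sxy
  Xs <- scale(X); Ys <- scale(Y)
  Sxx <- cov(Xs); Syy <- cov(Ys); Sxy <- cov(Xs, Ys)
  M <- solve(Syy) %*% t(Sxy) %*% solve(Sxx) %*% Sxy
  rhoOracle <- sqrt(sort(Re(eigen(M)$values), decreasing = TRUE))
  expect_lt(max(abs(fit$rho - rhoOracle)), 1e-8)

  # perfect linear relation: all rho = 1
  A <- matrix(rnorm(25), 5, 5) + diag(5)
  fitP <- ccaFit(X, X %*% A)
  expect_lt(max(abs(fitP$rho - 1)), 1e-8)

  # invariance to invertible affine transforms of either side
  B <- matrix(rnorm(16), 4, 4) + 2 * diag(4)
  fitT <- ccaFit(X %*% A, sweep(Y %*% B, 2, rnorm(4), "+"))
  expect_lt(max(abs(fitT$rho - fit$rho)), 1e-6)
})

test_that("null CCA correlations stay small at large n", {
  set.seed(8)
  X <- matrix(rnorm(5000 * 10), 5000, 10)
  Y <- matrix(rnorm(5000 * 10), 5000, 10)
  fit <- ccaFit(X, Y)
  expect_lt(max(fit$rho), 0.1)
  # small-n warning about inflated in-sample correlations
  expect_warning(ccaFit(X[1:30, ], Y[1:30, ]), "inflate")
})

test_that("canonical-correlation summaries use strict thresholds", {
  s <- ccaSummary(c(1, 1, 1))
  expect_equal(s$mean, 1); expect_equal(s$max, 1)
  expect_identical(c(s$nAbove0.3, s$nAbove0.5), c(3L, 3L))

  s2 <- ccaSummary(c(0.3, 0.5))
  expect_identical(c(s2$nAbove0.3, s2$nAbove0.5), c(1L, 0L))

  s3 <- ccaSummary(c(0.9, 0.6, 0.1))
  expect_equal(s3$mean, 0.5333333, tolerance = 1e-6)
  expect_equal(s3$max, 0.9)
  expect_identical(c(s3$nAbove0.3, s3$nAbove0.5), c(2L, 2L))
  expect_equal(s3$auc, s3$mean)
})
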