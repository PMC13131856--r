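test_that("embedding extraction is deterministic with the right shape", {
  coh <- tinyCohort(n = 5L, shape = c(8L, 8L, 8L))
  spec <- patchSpec(c(4L, 4L, 4L), coh@shape)
  pr <- initEncoderParams(tinyEncoderConfig(), spec, seed = 2L)
  e1 <- extractEmbeddings(pr, coh, "a", spec, batchSize = 2L)
  e2 <- extractEmbeddings(pr, coh, "a", spec, batchSize = 5L)
  expect_identical(dim(e1@values), c(5L, 8L, 16L))
  expect_equal(e1@values, e2@values, tolerance = 1e-12)
  expect_true(all(is.finite(e1@values)))
  # an untrained encoder is still a valid deterministic embedding
  eb <- extractEmbeddings(pr, coh, "b", spec)
  expect_false(isTRUE(all.equal(e1@values, eb@values)))
})

test_that("PCA reduction matches a covariance eigendecomposition oracle", {
  set.seed(7)
  n <- 50L; p <- 8L; w <- 5L
  mkEmb <- function(seed, mod) {
    set.seed(seed)
    new("EmbeddingTensor", values = array(rnorm(n * p * w), c(n, p, w)),
        subjectIds = sprintf("S%02d", 1:n), modality = mod)
  }
  ea <- mkEmb(1, "a"); eb <- mkEmb(2, "b")
  red <- pcaReduce(ea, eb, k = 6L, jointFit = TRUE)

  # oracle: eigendecomposition of the covariance of the stacked flattened
  # matrix (flattening reproduced independently)
  flat <- function(e) t(apply(e@values, 1, function(m) as.numeric(t(m))))
  X <- rbind(flat(ea), flat(eb))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  scoresOracle <- Xc %*% eg$vectors[, 1:6]
  got <- rbind(udipValues(red$a), udipValues(red$b))
  for (j in 1:6) {
    d1 <- max(abs(got[, j] - scoresOracle[, j]))
    d2 <- max(abs(got[, j] + scoresOracle[, j]))
    expect_lt(min(d1, d2), 1e-8)   # equality up to per-component sign
  }
  evOracle <- eg$values[1:6] / sum(eg$values)
  expect_equal(explainedVariance(red$a), evOracle, tolerance = 1e-10)

  # scores have zero column mean on the fitted stack
  expect_lt(max(abs(colMeans(got))), 1e-8)

  # joint basis maps identical inputs identically
  redSame <- pcaReduce(ea, ea, k = 3L, jointFit = TRUE)
  expect_equal(udipValues(redSame$a), udipValues(redSame$b),
               tolerance = 1e-12)
})

test_that("PCA handles exact low rank and the anticorrelated textbook case", {
  set.seed(11)
  n <- 40L
  basis <- matrix(rnorm(3 * 12), 3, 12)
  lowRank <- matrix(rnorm(n * 3), n, 3) %*% basis   # rank 3
  mk <- function(x, mod) new("EmbeddingTensor",
                             values = array(x, c(nrow(x), 1L, ncol(x))),
                             subjectIds = sprintf("S%02d", seq_len(nrow(x))),
                             modality = mod)
  red <- pcaReduce(mk(lowRank, "a"), mk(lowRank, "b"), k = 3L)
  expect_equal(sum(explainedVariance(red$a)), 1, tolerance = 1e-8)

  # two perfectly anticorrelated features: one component captures the
  # difference axis with |r| = 1
  z <- rnorm(n)
  anti <- cbind(z, -z)
  redA <- pcaReduce(mk(anti, "a"), mk(anti, "b"), k = 1L)
  expect_equal(abs(cor(udipValues(redA$a)[, 1], z)), 1, tolerance = 1e-10)

  expect_error(pcaReduce(mk(anti, "a"), mk(anti, "b"), k = 10L), "k must")
})

test_that("outlier masking is strict, per-entry and idempotent", {
  mkU <- function(m) new("UdipMatrix",
                         subjectIds = sprintf("S%03d", seq_len(nrow(m))),
                         udip = m,
                         explainedVariance = rep(1 / ncol(m), ncol(m)),
                         qcMask = matrix(TRUE, nrow(m), ncol(m)),
                         modality = "a")
  # gross outlier: exactly the extreme entry masked
  x <- matrix(0, 1000, 1); x[1000, 1] <- 100
  u <- outlierMask(mkU(x), 5)
  expect_identical(which(!qcMask(u)), 1000L)

  # all values within 1 SD: nothing masked
  set.seed(3)
  y <- matrix(runif(200, -0.5, 0.5), 100, 2)
  expect_true(all(qcMask(outlierMask(mkU(y), 5))))

  # idempotence
  u2 <- outlierMask(u, 5)
  expect_identical(qcMask(u2), qcMask(u))

  # zero-SD column: warning, no masking
  expect_warning(uz <- outlierMask(mkU(matrix(1, 50, 1)), 5), "zero SD")
  expect_true(all(qcMask(uz)))

  # Gaussian tail at z = 5 is ~5.7e-7: essentially nothing masked at n = 1e5
  set.seed(5)
  g <- matrix(rnorm(1e5), ncol = 1)
  expect_lte(sum(!qcMask(outlierMask(mkU(g), 5))), 3L)
})
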