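test_that("genotype generation respects contracts and Binomial(2,p) moments", {
  expect_error(genGenotypes(10L, 0L), "positive")
  expect_error(genGenotypes(0L, 10L), "positive")
  expect_error(genGenotypes(10L, 10L, mafRange = c(0, 0.5)), "mafRange")
  expect_error(genGenotypes(10L, 10L, mafRange = c(0.2, 0.6)), "mafRange")

  # mean dosage at p = 0.5 is 1 within CLT tolerance at n = 10,000
  panel <- genGenotypes(10000L, 20L, mafRange = c(0.5, 0.5), seed = 3L)
  expect_lt(max(abs(colMeans(dosages(panel)) - 1)), 0.02)
  expect_true(all(dosages(panel) %in% 0:2))

  # determinism: same seed, byte-identical panels
  p1 <- genGenotypes(50L, 30L, seed = 9L)
  p2 <- genGenotypes(50L, 30L, seed = 9L)
  expect_identical(dosages(p1), dosages(p2))
  expect_identical(as.data.frame(snpInfo(p1)), as.data.frame(snpInfo(p2)))

  # positions strictly increasing per chromosome, unique ids
  info <- snpInfo(p1)
  for (ch in unique(info$chrom))
    expect_false(is.unsorted(info$pos[info$chrom == ch], strictly = TRUE))
  expect_false(anyDuplicated(info$snpId) > 0)
})

test_that("latent generation matches its variance decomposition", {
  panel <- genGenotypes(10000L, 10L, seed = 5L)

  # null effects: z is pure noise with the requested SD
  lat0 <- genLatent(panel, integer(0), matrix(0, 0, 3), noiseSd = 0.7,
                    seed = 2L)
  expect_lt(max(abs(apply(latentFactors(lat0), 2, sd) / 0.7 - 1)), 0.05)

  # noiseless single causal SNP: z equals the standardized dosage
  lat1 <- genLatent(panel, 4L, matrix(1), noiseSd = 0, seed = 2L)
  g <- scale(dosages(panel)[, 4])
  expect_equal(as.numeric(latentFactors(lat1)), as.numeric(g),
               tolerance = 1e-12)

  # beta = 0.5, noise 1: R^2 of z on the SNP is 0.25/1.25 = 0.20 +/- 0.02
  lat2 <- genLatent(panel, 4L, matrix(0.5), noiseSd = 1, seed = 8L)
  r2 <- summary(lm(latentFactors(lat2)[, 1] ~ dosages(panel)[, 4]))$r.squared
  expect_lt(abs(r2 - 0.2), 0.02)

  expect_error(genLatent(panel, 99L, matrix(1)), "range")
})

test_that("latent variance bookkeeping holds at n = 5000", {
  panel <- genGenotypes(5000L, 20L, seed = 13L)
  beta <- matrix(0, 3, 2)
  beta[1, 1] <- 0.8; beta[2, 1] <- 0.3; beta[3, 2] <- 0.5
  lat <- genLatent(panel, c(2L, 9L, 17L), beta, noiseSd = 0.6, seed = 4L)
  v <- apply(latentFactors(lat), 2, var)
  expected <- colSums(beta^2) + 0.36
  expect_lt(max(abs(v / expected - 1)), 0.1)
})

test_that("paired rendering is a deterministic shared-latent construction", {
  panel <- genGenotypes(100L, 10L, seed = 21L)
  lat <- genLatent(panel, 3L, matrix(1), noiseSd = 0.2, seed = 21L)

  # identical z rows give identical volumes when noise is off
  latDup <- lat
  latDup@z[2, ] <- latDup@z[1, ]
  volsDup <- renderPairedVolumes(latDup, shape = c(6L, 6L, 6L),
                                 smoothSigma = 0, noiseSd = 0, seed = 3L)
  expect_identical(volsDup@volA[, , , 1], volsDup@volA[, , , 2])
  # modalities are distinct maps of the same latent
  expect_gt(max(abs(volsDup@volA[, , , 1] - volsDup@volB[, , , 1])), 1e-6)

  # across subjects, latent-driven voxels correlate across modalities while
  # the zero-loading control voxels do not
  vols <- renderPairedVolumes(lat, shape = c(6L, 6L, 6L), smoothSigma = 0,
                              noiseSd = 0.5, seed = 3L, nullFraction = 0.2)
  n <- 100L; V <- 216L
  a <- matrix(vols@volA, V, n); b <- matrix(vols@volB, V, n)
  sdA <- apply(a, 1, sd)
  # control voxels are exactly noise: locate them by reconstructing with
  # noise off
  clean <- renderPairedVolumes(lat, shape = c(6L, 6L, 6L), smoothSigma = 0,
                               noiseSd = 0, seed = 3L, nullFraction = 0.2)
  nullVox <- which(apply(matrix(clean@volA, V, n), 1, sd) == 0 &
                     apply(matrix(clean@volB, V, n), 1, sd) == 0)
  sigVox <- setdiff(seq_len(V), nullVox)
  corAB <- vapply(seq_len(V), function(v) cor(a[v, ], b[v, ]), numeric(1))
  expect_gt(length(nullVox), 10)
  expect_gt(mean(abs(corAB[sigVox])), mean(abs(corAB[nullVox])))
  expect_lt(mean(abs(corAB[nullVox])), 0.15)

  expect_error(renderPairedVolumes(lat, shape = c(6L, 6L)), "shape")
})

test_that("trait tables are linear in the latent and reproducible", {
  panel <- genGenotypes(60L, 10L, seed = 31L)
  lat <- genLatent(panel, c(2L, 7L), diag(2), noiseSd = 0.5, seed = 31L)

  tt0 <- genTraitTable(lat, qIdps = 5L, noiseSd = 0, seed = 6L)
  res <- lm(tt0@idps ~ latentFactors(lat))$residuals
  expect_lt(max(abs(res)), 1e-10)

  t1 <- genTraitTable(lat, qIdps = 5L, noiseSd = 0.4, seed = 6L)
  t2 <- genTraitTable(lat, qIdps = 5L, noiseSd = 0.4, seed = 6L)
  expect_identical(t1@idps, t2@idps)
  expect_identical(t1@covariates, t2@covariates)
  expect_error(genTraitTable(lat, qIdps = 0L), "positive")
})

test_that("simulateCohort is deterministic and splits private latents", {
  c1 <- simulateCohort(nSubjects = 12L, nSnps = 100L, shape = c(8L, 8L, 8L),
                       nCausal = 4L, d = 4L, seed = 5L)
  c2 <- simulateCohort(nSubjects = 12L, nSnps = 100L, shape = c(8L, 8L, 8L),
                       nCausal = 4L, d = 4L, seed = 5L)
  expect_identical(c1@volumes@volA, c2@volumes@volA)
  expect_identical(dosages(c1), dosages(c2))

  cp <- simulateCohort(nSubjects = 12L, nSnps = 100L, shape = c(8L, 8L, 8L),
                       nCausal = 4L, d = 4L, seed = 5L, sharedLatent = FALSE)
  expect_identical(cp@visibleDims$a, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(cp@visibleDims$b, c(FALSE, FALSE, TRUE, TRUE))
  # genotypes and latent identical across the paired conditions
  expect_identical(dosages(cp), dosages(c1))
  expect_identical(latentFactors(cp), latentFactors(c1))
})
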