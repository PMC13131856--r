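mkUdipFromMatrix <- function(m, ids = sprintf("S%04d", seq_len(nrow(m)))) {
  colnames(m) <- sprintf("UDIP_%d", seq_len(ncol(m)) - 1L)
  new("UdipMatrix", subjectIds = ids, udip = m,
      explainedVariance = rev(seq_len(ncol(m))) / sum(seq_len(ncol(m))),
      qcMask = matrix(TRUE, nrow(m), ncol(m)), modality = "a")
}

test_that("the residualized scan equals full multiple regression", {
  set.seed(21)
  n <- 150L
  panel <- genGenotypes(n, 30L, seed = 2L)
  cov <- data.frame(IID = subjectIds(panel), age = rnorm(n),
                    sex = rbinom(n, 1, 0.5))
  u <- mkUdipFromMatrix(cbind(rnorm(n), rnorm(n)), subjectIds(panel))
  res <- gwasScan(panel, u, cov, mafMin = 0)
  # oracle: per-SNP lm() with covariates entered directly
  for (s in c(1L, 7L, 23L)) for (j in 1:2) {
    fit <- summary(lm(u@udip[, j] ~ dosages(panel)[, s] + cov$age + cov$sex))
    co <- fit$coefficients[2, ]
    expect_equal(res@beta[s, j], unname(co[1]), tolerance = 1e-10)
    expect_equal(res@se[s, j], unname(co[2]), tolerance = 1e-10)
    expect_equal(res@p[s, j], unname(co[4]), tolerance = 1e-10)
  }
  expect_true(all(res@nUsed == n))
})

test_that("masked entries shrink the per-UDIP analysis sample", {
  set.seed(3)
  n <- 80L
  panel <- genGenotypes(n, 10L, seed = 5L)
  m <- cbind(rnorm(n), rnorm(n))
  u <- mkUdipFromMatrix(m, subjectIds(panel))
  u@qcMask[1:5, 2] <- FALSE
  res <- gwasScan(panel, u, NULL, mafMin = 0)
  expect_true(all(res@nUsed[, 1] == n))
  expect_true(all(res@nUsed[, 2] == n - 5L))
  # oracle on the reduced rows
  fit <- summary(lm(m[6:n, 2] ~ dosages(panel)[6:n, 4]))
  expect_equal(res@p[4, 2], unname(fit$coefficients[2, 4]),
               tolerance = 1e-10)
})

test_that("a planted SNP is detected and the null is calibrated (small)", {
  set.seed(31)
  n <- 500L
  panel <- genGenotypes(n, 200L, seed = 7L)
  g <- scale(dosages(panel)[, 50])
  u <- mkUdipFromMatrix(cbind(sqrt(0.1) * g + sqrt(0.9) * rnorm(n)),
                        subjectIds(panel))
  res <- gwasScan(panel, u, NULL, mafMin = 0)
  expect_lt(res@p[50, 1], 1e-8)
  # null SNPs: empirical type-I error near alpha
  pNull <- res@p[-50, 1]
  rate <- mean(pNull < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(pNull)) + 0.01)
})

test_that("minP aggregation takes row minima with first-index ties", {
  p <- rbind(c(0.5, 1e-9, 0.3), c(1, 1, 1), c(0.2, 0.2, 0.9))
  agg <- minpAggregate(p)
  expect_equal(agg$minp, c(1e-9, 1, 0.2))
  expect_identical(agg$bestUdip, c(2L, 1L, 1L))
  # single-UDIP input: minp is that vector
  one <- minpAggregate(matrix(c(0.4, 0.1), 2, 1))
  expect_equal(one$minp, c(0.4, 0.1))
})

test_that("dosage LD obeys its identities", {
  panel <- genGenotypes(2000L, 6L, seed = 9L)
  expect_equal(ldR2(panel, 2L, 2L), 1)
  # perfect allele flip: also r2 = 1
  flip <- panel
  flip@dosages[, 3] <- 2L - flip@dosages[, 2]
  expect_equal(ldR2(flip, 2L, 3L), 1, tolerance = 1e-12)
  # independently simulated SNPs are near-independent
  r2 <- replicate(20, {
    p2 <- genGenotypes(10000L, 2L, seed = sample.int(1e6, 1))
    ldR2(p2, 1L, 2L)
  })
  expect_gte(mean(r2 < 0.01), 0.9)
  mono <- panel
  mono@dosages[, 1] <- 1L
  expect_error(ldR2(mono, 1L, 2L), "monomorphic")
})

test_that("clumping follows the greedy lead/merge rules", {
  # build a panel with controlled positions and an LD-free structure
  set.seed(41)
  n <- 400L
  mkPanel <- function(nSnps, posList, chromList, dos) {
    info <- S4Vectors::DataFrame(
      chrom = chromList, snpId = sprintf("s%03d", seq_len(nSnps)),
      pos = posList,
      maf = pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2),
      A1 = rep("A", nSnps), A2 = rep("G", nSnps))
    new("GenotypePanel", dosages = dos,
        subjectIds = sprintf("S%04d", seq_len(n)), snpInfo = info)
  }
  mkSummary <- function(panel, minp) {
    nS <- ncol(panel@dosages)
    p <- matrix(minp, nS, 1, dimnames = list(panel@snpInfo$snpId, "UDIP_0"))
    new("GwasSummary", beta = p * 0, se = p * 0 + 1, tstat = p * 0,
        p = p, nUsed = matrix(n, nS, 1), minp = minp,
        bestUdip = rep(1L, nS), snpInfo = panel@snpInfo,
        udipNames = "UDIP_0")
  }

  # one significant SNP: a single point locus led by itself
  dos <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  pan1 <- mkPanel(3L, c(1e5, 2e5, 3e5), rep("chr1", 3), dos)
  s1 <- mkSummary(pan1, c(0.5, 1e-12, 0.5))
  l1 <- clumpLoci(s1, pan1, alpha = 1e-10)
  expect_length(l1, 1L)
  expect_equal(GenomicRanges::start(l1), 2e5)
  expect_equal(GenomicRanges::end(l1), 2e5)
  expect_identical(S4Vectors::mcols(l1)$leadSnp, "s002")

  # two independent significant SNPs 300 kb apart: two loci (gap >= 250 kb)
  pan2 <- mkPanel(2L, c(1e5, 4e5), rep("chr1", 2),
                  matrix(rbinom(n * 2, 2, 0.4), n, 2))
  s2 <- mkSummary(pan2, c(1e-12, 1e-11))
  expect_length(clumpLoci(s2, pan2, alpha = 1e-10), 2L)
  # and one merged locus when within 250 kb
  pan3 <- mkPanel(2L, c(1e5, 3e5), rep("chr1", 2),
                  matrix(rbinom(n * 2, 2, 0.4), n, 2))
  l3 <- clumpLoci(mkSummary(pan3, c(1e-12, 1e-11)), pan3, alpha = 1e-10)
  expect_length(l3, 1L)
  expect_equal(GenomicRanges::start(l3), 1e5)
  expect_equal(GenomicRanges::end(l3), 3e5)

  # no significant SNP: empty locus set, not an error
  expect_length(clumpLoci(mkSummary(pan2, c(0.5, 0.6)), pan2), 0L)
})

test_that("clumping agrees with a brute-force oracle on LD blocks", {
  set.seed(51)
  n <- 500L
  nSnps <- 50L
  # two planted LD blocks: SNPs 10-14 correlated, SNPs 30-34 correlated
  base1 <- rbinom(n, 2, 0.4); base2 <- rbinom(n, 2, 0.3)
  dos <- matrix(rbinom(n * nSnps, 2, 0.35), n, nSnps)
  for (k in 10:14) { flipRows <- sample(n, 50); g <- base1
    g[flipRows] <- rbinom(50, 2, 0.4); dos[, k] <- g }
  for (k in 30:34) { flipRows <- sample(n, 50); g <- base2
    g[flipRows] <- rbinom(50, 2, 0.3); dos[, k] <- g }
  info <- S4Vectors::DataFrame(
    chrom = rep("chr1", nSnps), snpId = sprintf("s%03d", 1:nSnps),
    pos = (1:nSnps) * 10000L,
    maf = pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2),
    A1 = rep("A", nSnps), A2 = rep("G", nSnps))
  panel <- new("GenotypePanel", dosages = dos,
               subjectIds = sprintf("S%04d", 1:n), snpInfo = info)
  minp <- runif(nSnps, 1e-12, 1e-11)
  summ <- new("GwasSummary",
              beta = matrix(0, nSnps, 1), se = matrix(1, nSnps, 1),
              tstat = matrix(0, nSnps, 1),
              p = matrix(minp, nSnps, 1,
                         dimnames = list(info$snpId, "UDIP_0")),
              nUsed = matrix(n, nSnps, 1), minp = minp,
              bestUdip = rep(1L, nSnps), snpInfo = info,
              udipNames = "UDIP_0")
  got <- clumpLoci(summ, panel, alpha = 1e-10, r2Max = 0.1, mergeKb = 30)

  # independent re-implementation of the same greedy + merge rules
  r2 <- cor(dos)^2
  ord <- order(minp, info$pos, info$snpId)
  remaining <- ord
  loci <- list()
  while (length(remaining)) {
    lead <- remaining[1]
    mem <- unique(c(lead, remaining[r2[lead, remaining] > 0.1]))
    loci[[length(loci) + 1]] <- list(start = min(info$pos[mem]),
                                     end = max(info$pos[mem]),
                                     top = min(minp[mem]))
    remaining <- setdiff(remaining, mem)
  }
  loci <- loci[order(vapply(loci, `[[`, 0, "start"))]
  merged <- list(loci[[1]])
  for (x in loci[-1]) {
    last <- merged[[length(merged)]]
    if (x$start - last$end < 30 * 1000) {
      merged[[length(merged)]] <- list(start = last$start,
                                       end = max(last$end, x$end),
                                       top = min(last$top, x$top))
    } else merged[[length(merged) + 1]] <- x
  }
  expect_length(got, length(merged))
  expect_equal(GenomicRanges::start(got),
               vapply(merged, `[[`, 0, "start"))
  expect_equal(GenomicRanges::end(got), vapply(merged, `[[`, 0, "end"))
  expect_equal(S4Vectors::mcols(got)$topP, vapply(merged, `[[`, 0, "top"))

  # every significant SNP in exactly one locus; loci non-overlapping
  allMembers <- unlist(strsplit(S4Vectors::mcols(got)$members, ","))
  expect_setequal(allMembers, info$snpId)
  expect_false(anyDuplicated(allMembers) > 0)
  if (length(got) > 1) {
    st <- GenomicRanges::start(got); en <- GenomicRanges::end(got)
    expect_true(all(st[-1] > en[-length(en)]))
  }
})

test_that("locus overlap matches the all-pairs clustering oracle", {
  # different chromosomes never overlap
  a <- locusSet("chr1", 100, 200)
  b <- locusSet("chr2", 100, 200)
  ov <- overlapLoci(a, b, padKb = 125)
  expect_identical(ov@shared, 0L)
  expect_identical(ov@total, 2L)

  # randomized oracle equivalence (padded, transitive clustering)
  for (s in 1:3) {
    set.seed(60 + s)
    nA <- 120L; nB <- 110L
    chA <- sample(paste0("chr", 1:5), nA, replace = TRUE)
    stA <- sample.int(3e7, nA); enA <- stA + sample.int(2e5, nA)
    chB <- sample(paste0("chr", 1:5), nB, replace = TRUE)
    stB <- sample.int(3e7, nB); enB <- stB + sample.int(2e5, nB)
    got <- overlapLoci(locusSet(chA, stA, enA), locusSet(chB, stB, enB))
    oracle <- bruteOverlapOracle(chA, stA, enA, chB, stB, enB)
    expect_identical(got@shared, as.integer(oracle$shared))
    expect_identical(got@uniqueA, as.integer(oracle$uniqueA))
    expect_identical(got@uniqueB, as.integer(oracle$uniqueB))
    expect_identical(got@total, as.integer(oracle$total))
    # partition identity
    expect_identical(got@shared + got@uniqueA + got@uniqueB, got@total)
  }
})

test_that("overlap partition arithmetic reproduces printed percentages", {
  ov <- overlapPartition(23, 14, 7)
  expect_identical(ov@total, 44L)
  expect_equal(round(ov@percentShared, 1), 52.3)
  ov2 <- overlapPartition(17, 0, 8)
  expect_identical(ov2@total, 25L)
  expect_identical(overlapPartition(0, 0, 0)@percentShared, 0)
})

test_that("novel loci are those missing from every reference", {
  t <- locusSet(rep("chr1", 3), c(1e6, 5e6, 9e6), c(1.1e6, 5.1e6, 9.1e6))
  expect_length(novelLoci(t, list()), 3L)
  expect_length(novelLoci(t, t), 0L)
  ref <- locusSet("chr1", 5.05e6, 5.2e6)
  nv <- novelLoci(t, ref, padKb = 10)
  expect_length(nv, 2L)
  expect_equal(GenomicRanges::start(nv), c(1e6, 9e6))
})
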