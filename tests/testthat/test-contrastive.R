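test_that("InfoNCE matches its closed forms", {
  d <- 8L
  q <- c(1, rep(0, d - 1))
  # negatives orthogonal to q, tau = 0.07: loss = log(1 + K exp(-1/tau))
  neg <- matrix(0, 4, d)
  neg[cbind(1:4, 2:5)] <- 1
  expect_equal(infoNCE(q, q, neg, 0.07), log(1 + 4 * exp(-1 / 0.07)),
               tolerance = 1e-9)

  # all similarities equal: loss = log(K + 1) exactly
  kPos <- q
  negSame <- matrix(rep(q, 16), 16, d, byrow = TRUE)
  expect_equal(infoNCE(q, kPos, negSame, 0.07), log(17), tolerance = 1e-12)

  # random high-dimensional draws: package loss equals a naive-formula
  # oracle, and the mean exceeds log(K + 1) by about half the logit
  # variance (sd of a random cosine is ~1/sqrt(d), scaled by 1/tau)
  set.seed(4)
  naive <- function(q, kp, ng, tau) {
    s <- c(sum(q * kp), as.numeric(ng %*% t(q))) / tau
    -s[1] + log(sum(exp(s)))
  }
  losses <- replicate(50, {
    q <- randUnitRows(1, 128, sample.int(1e6, 1))
    kp <- randUnitRows(1, 128, sample.int(1e6, 1))
    ng <- randUnitRows(1024, 128, sample.int(1e6, 1))
    expect_equal(infoNCE(q, kp, ng, 0.07), naive(q, kp, ng, 0.07),
                 tolerance = 1e-9)
    infoNCE(q, kp, ng, 0.07)
  })
  expect_gt(mean(losses), log(1025))
  expect_lt(mean(losses), log(1025) + 1.5)

  expect_error(infoNCE(2 * q, q, neg, 0.07), "unit-norm")
  expect_error(infoNCE(q, q, neg, -1), "positive")
  expect_gte(infoNCE(q, q, neg, 0.07), 0)
})

test_that("momentum update obeys its limits and arithmetic", {
  p <- list(a = matrix(1, 2, 2), b = rep(1, 3))
  k <- list(a = matrix(0, 2, 2), b = rep(0, 3))
  expect_identical(momentumUpdate(k, p, 1), k)
  expect_identical(momentumUpdate(k, p, 0), p)
  upd <- momentumUpdate(k, p, 0.999)
  expect_equal(upd$a[1, 1], 0.001, tolerance = 1e-15)
  expect_error(momentumUpdate(list(a = matrix(0, 3, 2), b = rep(0, 3)), p,
                              0.5), "shape")
})

test_that("a symmetric step is symmetric, FIFO-correct and norm-preserving", {
  setup <- tinyTrainSetup()
  tokA <- asNamespace("UDIPalign")$asTokenBatch(setup$cohort@volA, setup$spec)
  tokB <- asNamespace("UDIPalign")$asTokenBatch(setup$cohort@volB, setup$spec)
  st <- initContrastiveState(setup$enc, setup$spec, setup$con)
  P <- prod(gridDims(setup$spec))
  rows <- seq_len(4L * P)

  r1 <- symmetricStep(tokA[rows, ], tokB[rows, ], st, setup$con)
  r2 <- symmetricStep(tokB[rows, ], tokA[rows, ], st, setup$con)
  # swapping modality roles leaves the averaged loss unchanged
  expect_equal(r1$loss, r2$loss, tolerance = 1e-12)

  # FIFO: exactly B rows of each queue replaced, the rest bit-identical
  changedA <- which(rowSums(r1$state@queueA != st@queueA) > 0)
  changedB <- which(rowSums(r1$state@queueB != st@queueB) > 0)
  expect_identical(changedA, 1:4)
  expect_identical(changedB, 1:4)
  expect_identical(r1$state@queueA[-(1:4), ], st@queueA[-(1:4), ])
  expect_equal(max(abs(sqrt(rowSums(r1$state@queueA^2)) - 1)), 0,
               tolerance = 1e-5)
  expect_identical(r1$state@ptrA, 5L)
  expect_identical(r1$state@step, 1L)

  # batch larger than queue rejected
  conTiny <- contrastiveConfig(queueSize = 2L, batchSize = 2L, epochs = 1L)
  expect_error(symmetricStep(tokA[rows, ], tokB[rows, ], st, conTiny),
               "queue")
})

test_that("training reduces the loss on a toy cohort across seeds", {
  ok <- 0L
  for (s in 1:10) {
    setup <- tinyTrainSetup(n = 16L, seed = s)
    con <- contrastiveConfig(queueSize = 64L, epochs = 2L, batchSize = 8L,
                             lr = 1e-3, seed = s)
    tr <- trainContrastive(setup$cohort, setup$enc, con, spec = setup$spec)
    if (tr$epochLoss[2] <= tr$epochLoss[1]) ok <- ok + 1L
  }
  expect_gte(ok, 8L)
})

test_that("training is reproducible and epochs = 0 is a no-op", {
  setup <- tinyTrainSetup(n = 6L, seed = 2L)
  con0 <- contrastiveConfig(queueSize = 16L, epochs = 0L, batchSize = 4L,
                            seed = 2L)
  tr0 <- trainContrastive(setup$cohort, setup$enc, con0, spec = setup$spec)
  init <- initEncoderParams(setup$enc, setup$spec, seed = 2L)
  expect_identical(tr0$queryParams, init)
  expect_length(tr0$epochLoss, 0L)

  con <- contrastiveConfig(queueSize = 16L, epochs = 2L, batchSize = 4L,
                           lr = 1e-3, seed = 2L)
  trA <- trainContrastive(setup$cohort, setup$enc, con, spec = setup$spec)
  trB <- trainContrastive(setup$cohort, setup$enc, con, spec = setup$spec)
  expect_identical(trA$queryParams, trB$queryParams)
  expect_identical(trA$epochLoss, trB$epochLoss)
})

test_that("the key encoder lags the query encoder smoothly", {
  setup <- tinyTrainSetup(n = 8L, seed = 3L)
  con <- contrastiveConfig(queueSize = 32L, epochs = 3L, batchSize = 4L,
                           lr = 1e-3, momentum = 0.99, seed = 3L)
  tr <- trainContrastive(setup$cohort, setup$enc, con, spec = setup$spec)
  st <- tr$state
  gap <- function(a, b)
    sqrt(sum(vapply(names(a), function(nm) sum((a[[nm]] - b[[nm]])^2),
                    numeric(1))))
  # key differs from query (it lags) but not wildly
  g <- gap(st@keyParams, st@queryParams)
  expect_gt(g, 0)
  expect_lt(g, 1)
})

test_that("checkpoints round-trip the full training state", {
  setup <- tinyTrainSetup(n = 6L, seed = 8L)
  con <- contrastiveConfig(queueSize = 16L, epochs = 1L, batchSize = 3L,
                           lr = 1e-3, seed = 8L)
  tr <- trainContrastive(setup$cohort, setup$enc, con, spec = setup$spec)
  path <- file.path(withr::local_tempdir(), "ck.rds")
  saveCheckpoint(tr$state, setup$enc, setup$spec, path)
  back <- loadCheckpoint(path)
  expect_identical(back$state@queryParams, tr$state@queryParams)
  expect_identical(back$state@queueA, tr$state@queueA)
  expect_identical(back$state@step, tr$state@step)
  expect_identical(back$version, 1L)
  # the restored encoder reproduces embeddings exactly
  tok <- asNamespace("UDIPalign")$asTokenBatch(setup$cohort@volA, setup$spec)
  P <- prod(gridDims(setup$spec))
  expect_identical(encodePatches(back$state@queryParams, tok[seq_len(P), ]),
                   encodePatches(tr$queryParams, tok[seq_len(P), ]))
  saveRDS(list(a = 1), path)
  expect_error(loadCheckpoint(path), "checkpoint")
})
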