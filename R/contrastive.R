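#' Momentum-contrast training configurations
#'
#' \code{contrastiveConfig()} defaults to the full-scale reference configuration
#' (temperature 0.07, momentum 0.999, queue 65,536, AdamW lr 1e-4 with
#' cosine-annealing warm restarts T0=10, Tmult=2, etaMin=1e-6, 300 epochs);
#' \code{deskContrastiveConfig()} is the reduced profile used by the
#' package's examples and tests (queue 1,024, 20 epochs, batch 50, lr 1e-3).
#'
#' @param temperature,momentum,queueSize,lr,schedule,epochs,batchSize,weightDecay,seed
#'   see \code{\linkS4class{ContrastiveConfig}}.
#' @return a \code{ContrastiveConfig}.
#' @export
contrastiveConfig <- function(temperature = 0.07, momentum = 0.999,
                              queueSize = 65536L, lr = 1e-4,
                              schedule = c(T0 = 10, Tmult = 2, etaMin = 1e-6),
                              epochs = 300L, batchSize = 32L,
                              weightDecay = 0.01, seed = 1L) {
  new("ContrastiveConfig", temperature = temperature, momentum = momentum,
      queueSize = as.integer(queueSize), lr = lr, schedule = schedule,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      weightDecay = weightDecay, seed = as.integer(seed))
}

#' @rdname contrastiveConfig
#' @export
deskContrastiveConfig <- function(queueSize = 1024L, epochs = 20L,
                                  batchSize = 50L, lr = 1e-3, seed = 1L, ...) {
  contrastiveConfig(queueSize = queueSize, epochs = epochs,
                    batchSize = batchSize, lr = lr, seed = seed, ...)
}

checkUnitNorm <- function(x, label, tol = 1e-4) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  nrm <- sqrt(rowSums(x * x))
  if (any(abs(nrm - 1) > tol))
    stop(sprintf("%s must be unit-norm (max deviation %.2g)", label,
                 max(abs(nrm - 1))), call. = FALSE)
  x
}

#' InfoNCE contrastive loss
#'
#' Softmax cross-entropy of the positive similarity against the negative
#' similarities, scaled by the temperature:
#' \deqn{-\log \frac{e^{q\cdot k^+/\tau}}{e^{q\cdot k^+/\tau} +
#'   \sum_j e^{q\cdot k^-_j/\tau}}}
#' computed with log-sum-exp stabilization. With all similarities equal the
#' loss is exactly \code{log(K + 1)}.
#'
#' @param q unit-norm query vector (or matrix of row queries).
#' @param kPos unit-norm positive key (vector or matrix matching q).
#' @param negatives K x projDim matrix of unit-norm negative keys.
#' @param temperature positive scalar.
#' @return mean loss over query rows (non-negative scalar).
#' @export
infoNCE <- function(q, kPos, negatives, temperature = 0.07) {
  stopIfNot(temperature > 0, "temperature must be positive")
  q <- checkUnitNorm(q, "q")
  kPos <- checkUnitNorm(kPos, "kPos")
  negatives <- checkUnitNorm(negatives, "negatives")
  stopIfNot(nrow(q) == nrow(kPos), "q and kPos must pair up")
  infoNCEBatch(q, kPos, negatives, temperature)$loss
}

# batched loss + gradient w.r.t. q (mean over rows)
infoNCEBatch <- function(q, kPos, negatives, temperature) {
  B <- nrow(q)
  posLogit <- rowSums(q * kPos) / temperature
  negLogit <- (q %*% t(negatives)) / temperature          # B x K
  allLogit <- cbind(posLogit, negLogit)
  mx <- apply(allLogit, 1L, max)
  lse <- mx + log(rowSums(exp(allLogit - mx)))
  loss <- mean(lse - posLogit)
  prob <- exp(allLogit - lse)                             # softmax rows
  # d(mean loss)/dq_i = ((p_pos - 1) k+_i + sum_j p_ij k-_j) / (tau * B)
  dq <- ((prob[, 1L] - 1) * kPos + prob[, -1L, drop = FALSE] %*% negatives) /
    (temperature * B)
  list(loss = loss, dq = dq)
}

#' Momentum (exponential moving average) update of the key encoder
#'
#' Elementwise \code{theta_k <- m * theta_k + (1 - m) * theta_q} for every
#' parameter tensor.
#'
#' @param keyParams,queryParams congruent parameter lists.
#' @param m momentum coefficient in [0, 1].
#' @return updated key parameter list.
#' @export
momentumUpdate <- function(keyParams, queryParams, m) {
  stopIfNot(m >= 0 && m <= 1, "momentum must lie in [0, 1]")
  stopIfNot(identical(names(keyParams), names(queryParams)),
            "parameter sets must be congruent")
  for (nm in names(keyParams)) {
    if (!identical(dim(keyParams[[nm]]), dim(queryParams[[nm]])) ||
        length(keyParams[[nm]]) != length(queryParams[[nm]]))
      stop(sprintf("parameter %s shape mismatch", nm), call. = FALSE)
    keyParams[[nm]] <- m * keyParams[[nm]] + (1 - m) * queryParams[[nm]]
  }
  keyParams
}

#' Initialize the full contrastive training state
#'
#' Query parameters are drawn from the seeded initializer, the key encoder
#' starts as an exact copy, and both FIFO queues are pre-filled with random
#' unit vectors so the loss is well-defined from the first step.
#'
#' @param encCfg an \code{EncoderConfig}.
#' @param spec a \code{PatchSpec}.
#' @param conCfg a \code{ContrastiveConfig}.
#' @return a \code{\linkS4class{ContrastiveState}}.
#' @export
initContrastiveState <- function(encCfg, spec, conCfg) {
  qp <- initEncoderParams(encCfg, spec, seed = conCfg@seed)
  mkQueue <- function(seed) {
    m <- withSeed(seed,
                  matrix(stats::rnorm(conCfg@queueSize * encCfg@projDim),
                         conCfg@queueSize, encCfg@projDim))
    m / sqrt(rowSums(m * m))
  }
  # both queues start from the same draw so the symmetric objective is an
  # exact symmetry of the freshly initialized state; they diverge as
  # modality-specific keys are enqueued
  q0 <- mkQueue(subSeed(conCfg@seed, "queue"))
  new("ContrastiveState", queryParams = qp, keyParams = qp,
      queueA = q0, queueB = q0,
      ptrA = 1L, ptrB = 1L, step = 0L, lossTrace = numeric(0),
      optState = list())
}

# FIFO enqueue of B rows at the write pointer (wrapping); exactly B oldest
# entries are replaced, all other rows untouched.
enqueueRows <- function(queue, ptr, rows) {
  K <- nrow(queue)
  B <- nrow(rows)
  stopIfNot(B <= K, "batch larger than queue")
  idx <- ((ptr - 1L + seq_len(B) - 1L) %% K) + 1L
  queue[idx, ] <- rows
  list(queue = queue, ptr = ((ptr - 1L + B) %% K) + 1L)
}

# cosine-annealing warm-restart learning rate at fractional epoch t >= 0
cosineWarmRestartLr <- function(t, lr0, schedule) {
  T0 <- schedule[["T0"]]; Tm <- schedule[["Tmult"]]
  etaMin <- schedule[["etaMin"]]
  Ti <- T0
  tc <- t
  while (tc >= Ti) {
    tc <- tc - Ti
    Ti <- Ti * Tm
  }
  etaMin + (lr0 - etaMin) * (1 + cos(pi * tc / Ti)) / 2
}

adamwStep <- function(params, grads, opt, lr, weightDecay, b1 = 0.9,
                      b2 = 0.999, eps = 1e-8) {
  if (is.null(opt$t)) opt <- list(t = 0L, m = list(), v = list())
  opt$t <- opt$t + 1L
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- gr * 0
      opt$v[[nm]] <- gr * 0
    }
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * gr
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * gr * gr
    upd <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (upd + weightDecay * params[[nm]])
  }
  list(params = params, opt = opt)
}

asTokenBatch <- function(x, spec) {
  if (is.matrix(x)) return(x)
  dm <- dim(x)
  stopIfNot(length(dm) == 4L, "batch must be a token matrix or 4-D array")
  if (!identical(dm[1:3], as.integer(spec@padTo))) {
    padded <- array(0, dim = c(spec@padTo, dm[4]))
    for (i in seq_len(dm[4]))
      padded[, , , i] <- padVolume(x[, , , i], spec@padTo)
    x <- padded
  }
  tokenizeBatch(x, spec)
}

#' One symmetric momentum-contrast training step
#'
#' Computes the symmetric InfoNCE objective
#' \code{L = (L_{a->b} + L_{b->a}) / 2} in which each modality alternately
#' serves as query and key, backpropagates through the query encoder only,
#' applies one AdamW update, performs the momentum update of the key
#' encoder, and enqueues the key embeddings (modality-a keys into queue A,
#' modality-b keys into queue B; negatives are always drawn from the queue
#' of the current key's modality).
#'
#' @param batchA,batchB paired subject volumes: token matrices
#'   (B*nPatches x patchVoxels) or 4-D arrays (x, y, z, B); row/slot i of the
#'   two batches must belong to the same subject.
#' @param state a \code{ContrastiveState}.
#' @param conCfg a \code{ContrastiveConfig}.
#' @param spec a \code{PatchSpec} (needed when batches are 4-D arrays).
#' @param lr learning rate for this step (defaults to \code{conCfg@lr}).
#' @return list with \code{loss} and the updated \code{state}.
#' @export
symmetricStep <- function(batchA, batchB, state, conCfg, spec = NULL,
                          lr = conCfg@lr) {
  qp <- state@queryParams
  if (!is.null(spec)) {
    batchA <- asTokenBatch(batchA, spec)
    batchB <- asTokenBatch(batchB, spec)
  }
  P <- attr(qp, "nPatches")
  stopIfNot(nrow(batchA) == nrow(batchB), "paired batches must match")
  B <- nrow(batchA) %/% P
  stopIfNot(B <= conCfg@queueSize, "batch larger than queue")

  ka <- encForwardFast(state@keyParams, batchA, B)$z
  kb <- encForwardFast(state@keyParams, batchB, B)$z

  if (useCppBackend()) {
    depth <- attr(qp, "depth"); heads <- attr(qp, "heads")
    # branch a->b: query = modality a, key = modality b, negatives = queue B
    ab <- .encLossGradCpp(qp, batchA, B, depth, heads, kb, state@queueB,
                          conCfg@temperature, 0.5)
    ba <- .encLossGradCpp(qp, batchB, B, depth, heads, ka, state@queueA,
                          conCfg@temperature, 0.5)
    loss <- (ab$loss + ba$loss) / 2
    grads <- ab$grads
    for (nm in names(qp)) {
      g <- grads[[nm]] + ba$grads[[nm]]
      grads[[nm]] <- if (is.null(dim(qp[[nm]]))) as.numeric(g) else g
    }
  } else {
    fa <- encForward(qp, batchA, B, withCache = TRUE)
    fb <- encForward(qp, batchB, B, withCache = TRUE)
    ab <- infoNCEBatch(fa$cache$Z, kb, state@queueB, conCfg@temperature)
    ba <- infoNCEBatch(fb$cache$Z, ka, state@queueA, conCfg@temperature)
    loss <- (ab$loss + ba$loss) / 2
    gA <- encBackward(qp, fa$cache, ab$dq * 0.5)
    gB <- encBackward(qp, fb$cache, ba$dq * 0.5)
    grads <- gA
    for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + gB[[nm]]
  }

  up <- adamwStep(qp, grads, state@optState, lr, conCfg@weightDecay)
  state@queryParams <- up$params
  state@optState <- up$opt
  state@keyParams <- momentumUpdate(state@keyParams, state@queryParams,
                                    conCfg@momentum)
  ea <- enqueueRows(state@queueA, state@ptrA, ka)
  eb <- enqueueRows(state@queueB, state@ptrB, kb)
  state@queueA <- ea$queue; state@ptrA <- ea$ptr
  state@queueB <- eb$queue; state@ptrB <- eb$ptr
  state@step <- state@step + 1L
  state@lossTrace <- c(state@lossTrace, loss)
  list(loss = loss, state = state)
}

#' Train the symmetric multimodal momentum-contrast model
#'
#' Runs \code{epochs} passes over the cohort with seeded shuffling, applying
#' \code{\link{symmetricStep}} to each batch under the cosine-annealing
#' warm-restart learning-rate schedule, and records the per-epoch mean loss.
#' Fully reproducible given the config seed (single-threaded).
#'
#' @param cohort a \code{\linkS4class{PairedVolumeCohort}} (>= 2 subjects).
#' @param encCfg an \code{EncoderConfig}.
#' @param conCfg a \code{ContrastiveConfig}.
#' @param spec a \code{PatchSpec}; defaults to 8x8x8 patches on the cohort's
#'   own volume shape.
#' @return list with \code{state} (final \code{ContrastiveState}),
#'   \code{queryParams}, \code{epochLoss} (per-epoch mean loss) and
#'   \code{spec}.
#' @export
trainContrastive <- function(cohort, encCfg = deskEncoderConfig(),
                             conCfg = deskContrastiveConfig(), spec = NULL) {
  stopifnot(is(cohort, "PairedVolumeCohort"))
  n <- length(cohort@subjectIds)
  stopIfNot(n >= 2L, "cohort must contain at least 2 subjects")
  if (is.null(spec))
    spec <- patchSpec(c(8L, 8L, 8L), cohort@shape)
  tokA <- asTokenBatch(cohort@volA, spec)
  tokB <- asTokenBatch(cohort@volB, spec)
  P <- prod(gridDims(spec))
  state <- initContrastiveState(encCfg, spec, conCfg)
  epochLoss <- numeric(0)
  if (conCfg@epochs > 0L) {
    stepsPerEpoch <- max(1L, ceiling(n / conCfg@batchSize))
    for (ep in seq_len(conCfg@epochs)) {
      ord <- withSeed(subSeed(conCfg@seed, paste0("epoch", ep)), sample.int(n))
      batches <- split(ord, ceiling(seq_along(ord) / conCfg@batchSize))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        rows <- as.vector(outer(seq_len(P), (idx - 1L) * P, "+"))
        tEpoch <- (ep - 1L) + (bi - 1L) / stepsPerEpoch
        lr <- cosineWarmRestartLr(tEpoch, conCfg@lr, conCfg@schedule)
        res <- symmetricStep(tokA[rows, , drop = FALSE],
                             tokB[rows, , drop = FALSE],
                             state, conCfg, lr = lr)
        state <- res$state
        losses[bi] <- res$loss
      }
      epochLoss <- c(epochLoss, mean(losses))
    }
  }
  list(state = state, queryParams = state@queryParams, epochLoss = epochLoss,
       spec = spec)
}

#' Save / load a training checkpoint
#'
#' A checkpoint is a self-describing container (explicit \code{version}
#' field) holding the encoder configuration, the patch specification, both
#' parameter sets, the queue state and the step counter, so training can be
#' resumed or the frozen encoder reused for extraction.
#'
#' @param state a \code{\linkS4class{ContrastiveState}}.
#' @param encCfg the \code{EncoderConfig} used.
#' @param spec the \code{PatchSpec} used.
#' @param path file path (RDS container).
#' @return \code{saveCheckpoint}: invisibly, \code{path};
#'   \code{loadCheckpoint}: list with \code{state}, \code{encCfg},
#'   \code{spec}, \code{version}.
#' @export
saveCheckpoint <- function(state, encCfg, spec, path) {
  stopifnot(is(state, "ContrastiveState"), is(encCfg, "EncoderConfig"),
            is(spec, "PatchSpec"))
  saveRDS(list(version = 1L, format = "UDIPalign-checkpoint",
               state = state, encCfg = encCfg, spec = spec), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  stopIfNot(identical(ck$format, "UDIPalign-checkpoint"),
            "not a recognized checkpoint file")
  stopIfNot(identical(ck$version, 1L), "unsupported checkpoint version")
  list(state = ck$state, encCfg = ck$encCfg, spec = ck$spec,
       version = ck$version)
}
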