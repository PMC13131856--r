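# Shared tiny fixtures, built in code.

tinySpec <- function() patchSpec(c(2L, 2L, 2L), c(4L, 4L, 4L))

tinyEncoderConfig <- function()
  encoderConfig(depth = 1L, heads = 2L, width = 16L, projDim = 8L,
                mlpRatio = 2)

# a small paired-volume cohort rendered from a genuine shared latent
tinyCohort <- function(n = 8L, shape = c(8L, 8L, 8L), noiseSd = 0.2,
                       seed = 11L) {
  panel <- genGenotypes(n, 20L, seed = seed)
  lat <- genLatent(panel, c(5L, 15L), matrix(c(1, 0, 0, 1), 2, 2),
                   noiseSd = 0.3, seed = seed)
  renderPairedVolumes(lat, shape = shape, smoothSigma = 0,
                      noiseSd = noiseSd, seed = seed)
}

tinyTrainSetup <- function(n = 8L, seed = 11L) {
  coh <- tinyCohort(n = n, seed = seed)
  spec <- patchSpec(c(4L, 4L, 4L), coh@shape)
  enc <- tinyEncoderConfig()
  con <- contrastiveConfig(queueSize = 32L, epochs = 2L, batchSize = 4L,
                           lr = 1e-3, seed = seed)
  list(cohort = coh, spec = spec, enc = enc, con = con)
}

randUnitRows <- function(n, d, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(n * d), n, d)
  m / sqrt(rowSums(m * m))
}

# brute-force all-pairs interval overlap + transitive clustering oracle
bruteOverlapOracle <- function(chromA, startA, endA, chromB, startB, endB,
                               padKb = 125) {
  pad <- padKb * 1000
  df <- data.frame(
    chrom = c(chromA, chromB),
    start = pmax(1, c(startA, startB) - pad),
    end = c(endA, endB) + pad,
    src = rep(c("A", "B"), c(length(startA), length(startB))))
  n <- nrow(df)
  if (n == 0)
    return(list(shared = 0L, uniqueA = 0L, uniqueB = 0L, total = 0L))
  # all-pairs intersection scan (vectorized per anchor), then union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    hit <- j[df$chrom[j] == df$chrom[i] &
               df$start[i] <= df$end[j] & df$start[j] <= df$end[i]]
    for (jj in hit) {
      ri <- find(i); rj <- find(jj)
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  cl <- split(df$src, root)
  shared <- sum(vapply(cl, function(s) all(c("A", "B") %in% s), logical(1)))
  uniqueA <- sum(vapply(cl, function(s) all(s == "A"), logical(1)))
  uniqueB <- sum(vapply(cl, function(s) all(s == "B"), logical(1)))
  list(shared = shared, uniqueA = uniqueA, uniqueB = uniqueB,
       total = length(cl))
}
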