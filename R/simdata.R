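#' Simulate an additive genotype panel
#'
#' Draws per-SNP allele frequencies uniformly from \code{mafRange} and
#' dosages as Binomial(2, p) under Hardy-Weinberg equilibrium for unrelated
#' subjects. SNPs are split evenly across \code{nChrom} synthetic chromosomes
#' with positions spaced \code{spacingBp} apart (1-based).
#'
#' @param nSubjects,nSnps positive integers.
#' @param mafRange numeric(2) in (0, 0.5], allele-frequency sampling range.
#' @param nChrom number of synthetic chromosomes.
#' @param seed integer RNG seed (panel is a pure function of its arguments).
#' @param spacingBp inter-SNP spacing in base pairs (default 10 kb).
#' @return a \code{\linkS4class{GenotypePanel}}.
#' @export
genGenotypes <- function(nSubjects, nSnps, mafRange = c(0.05, 0.5),
                         nChrom = 2L, seed = 1L, spacingBp = 10000L) {
  stopIfNot(nSubjects > 0 && nSnps > 0,
            "nSubjects and nSnps must be positive")
  stopIfNot(length(mafRange) == 2L && mafRange[1] > 0 &&
              mafRange[1] <= mafRange[2] && mafRange[2] <= 0.5,
            "mafRange must satisfy 0 < low <= high <= 0.5")
  stopIfNot(nChrom > 0, "nChrom must be positive")
  withSeed(seed, {
    p <- stats::runif(nSnps, mafRange[1], mafRange[2])
    d <- matrix(stats::rbinom(nSubjects * nSnps, 2L, rep(p, each = nSubjects)),
                nrow = nSubjects, ncol = nSnps)
  })
  af <- colMeans(d) / 2
  maf <- pmin(af, 1 - af)
  # even split: first ceil(nSnps/nChrom) SNPs on chr1, etc.
  per <- ceiling(nSnps / nChrom)
  chrIdx <- rep(seq_len(nChrom), each = per)[seq_len(nSnps)]
  chrom <- paste0("chr", chrIdx)
  pos <- integer(nSnps)
  for (ch in unique(chrIdx))
    pos[chrIdx == ch] <- seq_len(sum(chrIdx == ch)) * spacingBp
  info <- DataFrame(chrom = chrom,
                    snpId = sprintf("snp%05d", seq_len(nSnps)),
                    pos = pos, maf = maf,
                    A1 = rep("A", nSnps), A2 = rep("G", nSnps))
  new("GenotypePanel", dosages = d,
      subjectIds = sprintf("S%04d", seq_len(nSubjects)), snpInfo = info)
}

#' Generate shared subject latent factors from causal SNPs
#'
#' Builds the ground-truth latent matrix \code{z = standardized(G[, causal])
#' \%*\% beta + eps}, \code{eps ~ N(0, noiseSd^2)}, so that the planted causal
#' SNPs drive every downstream quantity (volumes of both modalities, traits)
#' through a single shared latent.
#'
#' @param panel a \code{GenotypePanel}.
#' @param causalIdx integer indices of causal SNPs.
#' @param beta numeric matrix (length(causalIdx) x d) or vector (treated as a
#'   one-column matrix) of effects of standardized dosage on latent dims.
#' @param noiseSd non-negative noise standard deviation.
#' @param seed integer RNG seed.
#' @return a \code{\linkS4class{LatentCohort}}.
#' @export
genLatent <- function(panel, causalIdx, beta, noiseSd = 1, seed = 1L) {
  stopifnot(is(panel, "GenotypePanel"))
  causalIdx <- as.integer(causalIdx)
  nSnps <- ncol(panel@dosages)
  stopIfNot(all(causalIdx >= 1L & causalIdx <= nSnps),
            "causalIdx out of SNP index range")
  stopIfNot(noiseSd >= 0, "noiseSd must be >= 0")
  beta <- as.matrix(beta)
  stopIfNot(nrow(beta) == length(causalIdx),
            "beta must have one row per causal SNP")
  n <- nrow(panel@dosages)
  d <- ncol(beta)
  if (length(causalIdx)) {
    g <- panel@dosages[, causalIdx, drop = FALSE]
    gs <- standardizeCols(g)
    signal <- gs %*% beta
  } else signal <- matrix(0, n, d)
  eps <- withSeed(seed, matrix(stats::rnorm(n * d, sd = noiseSd), n, d))
  new("LatentCohort", z = signal + eps, subjectIds = panel@subjectIds,
      causalIdx = causalIdx, beta = beta)
}

# separable 3-D Gaussian smoothing of a (x, y, z, n) array; sigma in voxels
smoothGaussian3D <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  convAxis <- function(a, axis) {
    dm <- dim(a)
    nd <- dm[axis]
    # banded convolution matrix with zero boundary
    K <- matrix(0, nd, nd)
    for (off in seq(-r, r)) {
      i <- seq_len(nd)
      j <- i + off
      ok <- j >= 1 & j <= nd
      K[cbind(i[ok], j[ok])] <- k[off + r + 1]
    }
    perm <- c(axis, setdiff(seq_along(dm), axis))
    ap <- aperm(a, perm)
    m <- K %*% matrix(ap, nrow = nd)
    out <- array(m, dim = dm[perm])
    aperm(out, order(perm))
  }
  for (ax in 1:3) v <- convAxis(v, ax)
  v
}

#' Render paired 3D volumes from a shared latent
#'
#' Each modality's volume is a fixed seed-derived linear map of the subject
#' latent, Gaussian-smoothed, plus i.i.d. voxel noise:
#' \code{vol = smooth(W_mu \%*\% z) + eps}. The two modality maps
#' \code{W_a != W_b} are independent draws, so the modalities are distinct
#' renderings of the same latent. A random subset of voxels
#' (\code{nullFraction}) has zero latent loading in both modalities, giving
#' pure-noise control voxels (exactly noise-only when \code{smoothSigma = 0}).
#'
#' @param latent a \code{LatentCohort}.
#' @param shape integer(3) voxel grid.
#' @param smoothSigma Gaussian smoothing sigma in voxels (0 disables).
#' @param noiseSd voxel noise SD.
#' @param seed integer RNG seed (maps and noise are derived sub-streams).
#' @param visibleDims list(a =, b =) of logical vectors over latent columns;
#'   a column rendered only into one modality creates modality-private
#'   structure. Default: all columns visible to both.
#' @param nullFraction fraction of voxels with zero loading in both maps.
#' @return a \code{\linkS4class{PairedVolumeCohort}}.
#' @export
renderPairedVolumes <- function(latent, shape = c(32L, 32L, 32L),
                                smoothSigma = 1, noiseSd = 0.2, seed = 1L,
                                visibleDims = NULL, nullFraction = 0.05) {
  stopifnot(is(latent, "LatentCohort"))
  shape <- as.integer(shape)
  stopIfNot(length(shape) == 3L && all(shape > 0L), "shape must be 3 positive ints")
  z <- latent@z
  n <- nrow(z); d <- ncol(z); V <- prod(shape)
  if (is.null(visibleDims))
    visibleDims <- list(a = rep(TRUE, d), b = rep(TRUE, d))
  stopIfNot(length(visibleDims$a) == d && length(visibleDims$b) == d,
            "visibleDims vectors must match latent dimensionality")
  mk <- function(stream, visible) {
    W <- withSeed(subSeed(seed, stream),
                  matrix(stats::rnorm(d * V, sd = 1 / sqrt(max(1, d))), d, V))
    W[!visible, ] <- 0
    W
  }
  Wa <- mk("renderWa", visibleDims$a)
  Wb <- mk("renderWb", visibleDims$b)
  nullVox <- withSeed(subSeed(seed, "nullvox"),
                      sample.int(V, size = floor(nullFraction * V)))
  Wa[, nullVox] <- 0
  Wb[, nullVox] <- 0
  render <- function(W, stream) {
    sig <- z %*% W                                   # n x V
    a <- array(t(sig), dim = c(shape, n))
    a <- smoothGaussian3D(a, smoothSigma)
    if (noiseSd > 0)
      a <- a + withSeed(subSeed(seed, stream),
                        array(stats::rnorm(length(a), sd = noiseSd), dim = dim(a)))
    a
  }
  new("PairedVolumeCohort", subjectIds = latent@subjectIds,
      volA = render(Wa, "noiseA"), volB = render(Wb, "noiseB"),
      shape = shape)
}

#' Generate a synthetic trait table
#'
#' Traits (stand-ins for conventional IDPs) are linear functions of the
#' shared latent plus noise: \code{idps = z \%*\% L + eps} with a seed-derived
#' loading matrix \code{L}. Covariates are age ~ Uniform(45, 80)
#' (standardized) and sex ~ Bernoulli(0.5) coded 0/1.
#'
#' @param latent a \code{LatentCohort}.
#' @param qIdps number of traits (> 0).
#' @param loadingSd SD of the N(0, loadingSd^2) entries of L.
#' @param noiseSd trait noise SD.
#' @param seed integer RNG seed.
#' @return a \code{\linkS4class{TraitTable}}.
#' @export
genTraitTable <- function(latent, qIdps = 20L, loadingSd = 1, noiseSd = 0.5,
                          seed = 1L) {
  stopifnot(is(latent, "LatentCohort"))
  stopIfNot(qIdps > 0, "qIdps must be positive")
  z <- latent@z
  n <- nrow(z); d <- ncol(z)
  L <- withSeed(subSeed(seed, "traitload"),
                matrix(stats::rnorm(d * qIdps, sd = loadingSd), d, qIdps))
  eps <- withSeed(subSeed(seed, "traitnoise"),
                  matrix(stats::rnorm(n * qIdps, sd = noiseSd), n, qIdps))
  idps <- z %*% L + eps
  colnames(idps) <- sprintf("IDP_%03d", seq_len(qIdps))
  cov <- withSeed(subSeed(seed, "covariates"), {
    age <- stats::runif(n, 45, 80)
    sex <- stats::rbinom(n, 1L, 0.5)
    data.frame(age = as.numeric(scale(age)), sex = sex)
  })
  new("TraitTable", subjectIds = latent@subjectIds, idps = idps,
      covariates = cov)
}

#' Simulate a full multimodal imaging-genetics cohort
#'
#' One master seed spawns independent sub-streams for genotypes, latent
#' noise, volume rendering and traits. Defaults define the package's desk
#' scale: 200 subjects, 2,000 SNPs on 2 chromosomes, 8 latent dimensions
#' driven by 8 causal SNPs (one per dimension, effect 1 on the standardized
#' dosage scale), 32^3 voxel volumes.
#'
#' With \code{sharedLatent = FALSE} the latent dimensions are split between
#' the modalities (first half rendered only into modality a, second half only
#' into b), creating modality-private genetic architecture for
#' overlap-contrast experiments; causal SNPs and effects are unchanged.
#'
#' @param nSubjects,nSnps,nChrom,mafRange see \code{\link{genGenotypes}}.
#' @param d latent dimensionality.
#' @param nCausal number of causal SNPs (assigned round-robin to latent
#'   dimensions).
#' @param causalBeta per-SNP effect size on its latent dimension.
#' @param latentNoiseSd,smoothSigma,volNoiseSd,shape rendering parameters.
#' @param qIdps,traitNoiseSd trait-table parameters.
#' @param sharedLatent logical; FALSE renders modality-private latents.
#' @param seed master seed.
#' @return a \code{\linkS4class{SyntheticCohort}}.
#' @export
simulateCohort <- function(nSubjects = 200L, nSnps = 2000L, nChrom = 2L,
                           mafRange = c(0.05, 0.5), d = 8L, nCausal = 8L,
                           causalBeta = 1, latentNoiseSd = 0.5,
                           shape = c(32L, 32L, 32L), smoothSigma = 1,
                           volNoiseSd = 0.2, qIdps = 20L, traitNoiseSd = 0.5,
                           sharedLatent = TRUE, seed = 1L) {
  panel <- genGenotypes(nSubjects, nSnps, mafRange, nChrom,
                        seed = subSeed(seed, "genotypes"))
  # causal SNPs spread evenly over the panel, one latent dim each (round-robin)
  causalIdx <- as.integer(round(seq(1, nSnps, length.out = nCausal + 2L)))[
    seq_len(nCausal) + 1L]
  beta <- matrix(0, nCausal, d)
  beta[cbind(seq_len(nCausal), rep_len(seq_len(d), nCausal))] <- causalBeta
  latent <- genLatent(panel, causalIdx, beta, noiseSd = latentNoiseSd,
                      seed = subSeed(seed, "latent"))
  visible <- if (sharedLatent) {
    list(a = rep(TRUE, d), b = rep(TRUE, d))
  } else {
    half <- floor(d / 2)
    list(a = seq_len(d) <= half, b = seq_len(d) > half)
  }
  vols <- renderPairedVolumes(latent, shape = shape, smoothSigma = smoothSigma,
                              noiseSd = volNoiseSd,
                              seed = subSeed(seed, "render"),
                              visibleDims = visible)
  traits <- genTraitTable(latent, qIdps = qIdps, noiseSd = traitNoiseSd,
                          seed = subSeed(seed, "traits"))
  new("SyntheticCohort", genotypes = panel, latent = latent, volumes = vols,
      traits = traits, visibleDims = visible)
}
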