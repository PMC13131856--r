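#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' GenotypePanel: additive genotype dosages with SNP metadata
#'
#' Container for a subjects-by-SNPs dosage matrix (values 0/1/2 copies of the
#' effect allele) together with per-SNP metadata (chromosome, 1-based
#' position, realized minor-allele frequency, allele labels).
#'
#' @slot dosages integer-valued matrix, subjects x SNPs.
#' @slot subjectIds character vector of subject identifiers (IIDs).
#' @slot snpInfo \code{DataFrame} with columns \code{chrom}, \code{snpId},
#'   \code{pos}, \code{maf}, \code{A1}, \code{A2}; one row per SNP, positions
#'   strictly increasing within each chromosome.
#'
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  representation(
    dosages = "matrix",
    subjectIds = "character",
    snpInfo = "DataFrame"
  )
)

setValidity("GenotypePanel", function(object) {
  msg <- character()
  d <- object@dosages
  if (nrow(d) != length(object@subjectIds))
    msg <- c(msg, "nrow(dosages) must equal length(subjectIds)")
  if (ncol(d) != nrow(object@snpInfo))
    msg <- c(msg, "ncol(dosages) must equal nrow(snpInfo)")
  if (length(d) && (any(!d %in% c(0, 1, 2))))
    msg <- c(msg, "dosages must take values in {0, 1, 2}")
  req <- c("chrom", "snpId", "pos", "maf")
  if (!all(req %in% colnames(object@snpInfo)))
    msg <- c(msg, sprintf("snpInfo must contain columns %s",
                          paste(req, collapse = ", ")))
  else {
    if (anyDuplicated(object@snpInfo$snpId))
      msg <- c(msg, "snpIds must be unique")
    for (ch in unique(object@snpInfo$chrom)) {
      p <- object@snpInfo$pos[object@snpInfo$chrom == ch]
      if (is.unsorted(p, strictly = TRUE))
        msg <- c(msg, sprintf("positions not strictly increasing on %s", ch))
    }
  }
  if (anyDuplicated(object@subjectIds))
    msg <- c(msg, "subjectIds must be unique")
  if (length(msg)) msg else TRUE
})

#' LatentCohort: shared subject latent factors with causal bookkeeping
#'
#' Ground-truth latent matrix underlying a synthetic cohort: each subject has
#' a d-dimensional latent vector driven additively by a set of causal SNPs.
#'
#' @slot z numeric matrix, subjects x d.
#' @slot subjectIds character subject identifiers.
#' @slot causalIdx integer indices (into the genotype panel's SNP axis) of
#'   the causal SNPs.
#' @slot beta numeric matrix, causal SNPs x d, effects of the standardized
#'   causal dosages on each latent dimension.
#'
#' @exportClass LatentCohort
setClass("LatentCohort",
  representation(
    z = "matrix",
    subjectIds = "character",
    causalIdx = "integer",
    beta = "matrix"
  )
)

setValidity("LatentCohort", function(object) {
  msg <- character()
  if (nrow(object@z) != length(object@subjectIds))
    msg <- c(msg, "nrow(z) must equal length(subjectIds)")
  if (length(object@z) && !all(is.finite(object@z)))
    msg <- c(msg, "z must be finite")
  if (length(object@causalIdx) != nrow(object@beta))
    msg <- c(msg, "length(causalIdx) must equal nrow(beta)")
  if (nrow(object@beta) > 0 && ncol(object@beta) != ncol(object@z))
    msg <- c(msg, "ncol(beta) must equal ncol(z)")
  if (length(msg)) msg else TRUE
})

#' PairedVolumeCohort: paired 3D volumes for two modalities
#'
#' Per-subject paired volumetric images (two modality renderings of the same
#' subject), stored as 4-D arrays with the subject on the last axis.
#'
#' @slot subjectIds character subject identifiers.
#' @slot volA,volB numeric 4-D arrays with dim c(shape, n subjects).
#' @slot shape integer(3) voxel grid dimensions.
#'
#' @exportClass PairedVolumeCohort
setClass("PairedVolumeCohort",
  representation(
    subjectIds = "character",
    volA = "array",
    volB = "array",
    shape = "integer"
  )
)

setValidity("PairedVolumeCohort", function(object) {
  msg <- character()
  n <- length(object@subjectIds)
  exp_dim <- c(object@shape, n)
  if (!identical(dim(object@volA), as.integer(exp_dim)))
    msg <- c(msg, "volA must have dim c(shape, n)")
  if (!identical(dim(object@volB), as.integer(exp_dim)))
    msg <- c(msg, "volB must have dim c(shape, n)")
  if (length(object@shape) != 3L)
    msg <- c(msg, "shape must be length 3")
  if (length(msg)) msg else TRUE
})

#' TraitTable: per-subject traits and covariates
#'
#' Stand-in for conventional imaging-derived phenotype (IDP) tables: a block
#' of quantitative traits plus the usual GWAS covariates (age, sex, ...).
#'
#' @slot subjectIds character subject identifiers (one row per subject).
#' @slot idps numeric matrix, subjects x traits.
#' @slot covariates data.frame of covariates, subjects x c.
#'
#' @exportClass TraitTable
setClass("TraitTable",
  representation(
    subjectIds = "character",
    idps = "matrix",
    covariates = "data.frame"
  )
)

setValidity("TraitTable", function(object) {
  msg <- character()
  if (anyDuplicated(object@subjectIds))
    msg <- c(msg, "duplicated subjectIds")
  if (nrow(object@idps) != length(object@subjectIds))
    msg <- c(msg, "idps rows must match subjectIds")
  if (nrow(object@covariates) != length(object@subjectIds))
    msg <- c(msg, "covariate rows must match subjectIds")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: bundled synthetic multimodal imaging-genetics cohort
#'
#' The output of \code{\link{simulateCohort}}: genotypes, ground-truth
#' latents, paired volumes and a trait table, all keyed by subject ID.
#'
#' @slot genotypes a \code{GenotypePanel}.
#' @slot latent a \code{LatentCohort}.
#' @slot volumes a \code{PairedVolumeCohort}.
#' @slot traits a \code{TraitTable}.
#' @slot visibleDims list with logical vectors \code{a} and \code{b} marking
#'   which latent columns are rendered into each modality (supports
#'   modality-private latent dimensions).
#'
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(
    genotypes = "GenotypePanel",
    latent = "LatentCohort",
    volumes = "PairedVolumeCohort",
    traits = "TraitTable",
    visibleDims = "list"
  )
)

#' PatchSpec: volume padding and patch tiling specification
#'
#' @slot patchSize integer(3) patch dimensions in voxels.
#' @slot padTo integer(3) target padded volume shape; must be divisible by
#'   \code{patchSize} axis-wise.
#'
#' @exportClass PatchSpec
setClass("PatchSpec",
  representation(patchSize = "integer", padTo = "integer"))

setValidity("PatchSpec", function(object) {
  msg <- character()
  if (length(object@patchSize) != 3L || length(object@padTo) != 3L)
    msg <- c(msg, "patchSize and padTo must be length 3")
  else {
    if (any(object@patchSize < 1L) || any(object@padTo < 1L))
      msg <- c(msg, "dimensions must be positive")
    if (any(object@padTo %% object@patchSize != 0L))
      msg <- c(msg, "padTo must be divisible by patchSize in every axis")
  }
  if (length(msg)) msg else TRUE
})

#' EncoderConfig: vision-transformer encoder hyperparameters
#'
#' @slot depth integer, number of transformer layers.
#' @slot heads integer, attention heads per layer.
#' @slot width integer, token embedding dimension (divisible by heads).
#' @slot projDim integer, contrastive projection dimension.
#' @slot mlpRatio numeric, hidden width of the transformer MLP as a multiple
#'   of \code{width}.
#'
#' @exportClass EncoderConfig
setClass("EncoderConfig",
  representation(depth = "integer", heads = "integer", width = "integer",
                 projDim = "integer", mlpRatio = "numeric"))

setValidity("EncoderConfig", function(object) {
  msg <- character()
  if (any(c(object@depth, object@heads, object@width, object@projDim) < 1L))
    msg <- c(msg, "all encoder dimensions must be positive")
  if (object@width %% object@heads != 0L)
    msg <- c(msg, "width must be divisible by heads")
  if (object@mlpRatio <= 0)
    msg <- c(msg, "mlpRatio must be positive")
  if (length(msg)) msg else TRUE
})

#' ContrastiveConfig: momentum-contrast training hyperparameters
#'
#' Defaults follow the full-scale reference configuration: temperature 0.07, key-encoder
#' momentum 0.999, queue of 65,536 entries, AdamW with initial learning rate
#' 1e-4 under cosine-annealing warm restarts (T0 = 10, Tmult = 2,
#' etaMin = 1e-6), 300 epochs.
#'
#' @slot temperature positive numeric, InfoNCE temperature.
#' @slot momentum numeric in [0,1], key-encoder moving-average coefficient.
#' @slot queueSize integer, FIFO negative-queue length (>= batchSize).
#' @slot lr numeric, initial learning rate.
#' @slot schedule named numeric c(T0=, Tmult=, etaMin=) cosine-annealing
#'   warm-restart schedule.
#' @slot epochs integer, training epochs.
#' @slot batchSize integer.
#' @slot weightDecay numeric, AdamW decoupled weight decay.
#' @slot seed integer RNG seed for initialization and shuffling.
#'
#' @exportClass ContrastiveConfig
setClass("ContrastiveConfig",
  representation(temperature = "numeric", momentum = "numeric",
                 queueSize = "integer", lr = "numeric", schedule = "numeric",
                 epochs = "integer", batchSize = "integer",
                 weightDecay = "numeric", seed = "integer"))

setValidity("ContrastiveConfig", function(object) {
  msg <- character()
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (object@momentum < 0 || object@momentum > 1)
    msg <- c(msg, "momentum must lie in [0, 1]")
  if (object@queueSize < object@batchSize)
    msg <- c(msg, "queueSize must be >= batchSize")
  if (!all(c("T0", "Tmult", "etaMin") %in% names(object@schedule)))
    msg <- c(msg, "schedule needs named entries T0, Tmult, etaMin")
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ContrastiveState: full state of momentum-contrast training
#'
#' Query and key parameter sets, the two per-modality FIFO negative queues
#' (rows unit-norm, fixed size from initialization on), optimizer moments,
#' the global step counter and the loss trace.
#'
#' @slot queryParams,keyParams named lists of parameter arrays (congruent).
#' @slot queueA,queueB queueSize x projDim matrices of unit-norm rows.
#' @slot ptrA,ptrB integer write pointers (next row to overwrite).
#' @slot step integer global step counter.
#' @slot lossTrace numeric per-step losses.
#' @slot optState list, AdamW first/second moment estimates.
#'
#' @exportClass ContrastiveState
setClass("ContrastiveState",
  representation(queryParams = "list", keyParams = "list",
                 queueA = "matrix", queueB = "matrix",
                 ptrA = "integer", ptrB = "integer",
                 step = "integer", lossTrace = "numeric",
                 optState = "list"))

setValidity("ContrastiveState", function(object) {
  msg <- character()
  if (!identical(dim(object@queueA), dim(object@queueB)))
    msg <- c(msg, "queues must have identical dimensions")
  for (qn in c("queueA", "queueB")) {
    q <- slot(object, qn)
    if (nrow(q)) {
      nrm <- sqrt(rowSums(q^2))
      if (any(abs(nrm - 1) > 1e-5))
        msg <- c(msg, sprintf("%s rows must be unit-norm", qn))
    }
  }
  if (!identical(sort(names(object@queryParams)),
                 sort(names(object@keyParams))))
    msg <- c(msg, "query and key parameter sets must be congruent")
  if (length(msg)) msg else TRUE
})

#' EmbeddingTensor: frozen-encoder patch embeddings
#'
#' @slot values numeric 3-D array, subjects x patches x width.
#' @slot subjectIds character.
#' @slot modality character scalar tag ("a" or "b").
#'
#' @exportClass EmbeddingTensor
setClass("EmbeddingTensor",
  representation(values = "array", subjectIds = "character",
                 modality = "character"))

setValidity("EmbeddingTensor", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-D array")
  else if (dim(object@values)[1] != length(object@subjectIds))
    msg <- c(msg, "first dim of values must match subjectIds")
  if (length(object@values) && !all(is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' UdipMatrix: latent imaging phenotypes with QC mask
#'
#' Subjects x K matrix of unsupervised-learning-derived imaging phenotypes
#' (UDIPs), PCA component scores of flattened patch embeddings, together with
#' per-component explained-variance ratios and a per-entry QC mask
#' (FALSE = entry excluded downstream).
#'
#' @slot subjectIds character.
#' @slot udip numeric matrix subjects x K, columns ordered by decreasing
#'   explained variance.
#' @slot explainedVariance numeric length-K explained-variance ratios.
#' @slot qcMask logical matrix, same dim as udip.
#' @slot modality character tag.
#'
#' @exportClass UdipMatrix
setClass("UdipMatrix",
  representation(subjectIds = "character", udip = "matrix",
                 explainedVariance = "numeric", qcMask = "matrix",
                 modality = "character"))

setValidity("UdipMatrix", function(object) {
  msg <- character()
  if (nrow(object@udip) != length(object@subjectIds))
    msg <- c(msg, "udip rows must match subjectIds")
  if (ncol(object@udip) != length(object@explainedVariance))
    msg <- c(msg, "explainedVariance must have one entry per component")
  if (is.unsorted(-object@explainedVariance))
    msg <- c(msg, "components must be ordered by decreasing explained variance")
  if (!identical(dim(object@qcMask), dim(object@udip)))
    msg <- c(msg, "qcMask must match udip dimensions")
  if (length(msg)) msg else TRUE
})

#' GwasSummary: per-SNP, per-UDIP association statistics
#'
#' OLS association statistics for every (SNP, UDIP) pair plus the per-SNP
#' minP aggregate (minimum p over the UDIP axis, ties broken by lowest UDIP
#' index).
#'
#' @slot beta,se,tstat,p numeric matrices, SNPs x UDIPs.
#' @slot nUsed integer matrix of per-test sample sizes.
#' @slot minp numeric per-SNP minimum p-value across UDIPs.
#' @slot bestUdip integer index of the UDIP achieving minp.
#' @slot snpInfo \code{DataFrame}, metadata for the retained SNPs.
#' @slot udipNames character.
#'
#' @exportClass GwasSummary
setClass("GwasSummary",
  representation(beta = "matrix", se = "matrix", tstat = "matrix",
                 p = "matrix", nUsed = "matrix", minp = "numeric",
                 bestUdip = "integer", snpInfo = "DataFrame",
                 udipNames = "character"))

setValidity("GwasSummary", function(object) {
  msg <- character()
  dm <- dim(object@p)
  for (s in c("beta", "se", "tstat", "nUsed"))
    if (!identical(dim(slot(object, s)), dm))
      msg <- c(msg, sprintf("%s must match dim(p)", s))
  if (nrow(object@p) != length(object@minp))
    msg <- c(msg, "minp must have one entry per SNP")
  if (length(object@p) && (any(object@p <= 0 | object@p > 1, na.rm = TRUE)))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (nrow(object@p) != nrow(object@snpInfo))
    msg <- c(msg, "snpInfo must have one row per SNP")
  if (length(msg)) msg else TRUE
})

#' OverlapResult: cross-set locus overlap partition
#'
#' Union-clusters of padded loci from two locus sets, partitioned into
#' shared (members from both sets), unique to A and unique to B;
#' \code{shared + uniqueA + uniqueB == total} always holds and
#' \code{percentShared = 100 * shared / total}.
#'
#' @slot shared,uniqueA,uniqueB,total integer cluster counts.
#' @slot percentShared numeric.
#' @slot clusters a \code{GRanges} of cluster intervals with membership
#'   annotation in \code{mcols}.
#'
#' @exportClass OverlapResult
setClass("OverlapResult",
  representation(shared = "integer", uniqueA = "integer", uniqueB = "integer",
                 total = "integer", percentShared = "numeric",
                 clusters = "ANY"))

setValidity("OverlapResult", function(object) {
  msg <- character()
  if (object@shared + object@uniqueA + object@uniqueB != object@total)
    msg <- c(msg, "shared + uniqueA + uniqueB must equal total")
  expect <- if (object@total == 0L) 0 else 100 * object@shared / object@total
  if (abs(object@percentShared - expect) > 1e-8)
    msg <- c(msg, "percentShared inconsistent with counts")
  if (length(msg)) msg else TRUE
})

#' AlignmentReport: cross-modal alignment summary
#'
#' @slot ckaPos,ckaNeg numeric vectors of bootstrap / permutation CKA values.
#' @slot ccaRho numeric canonical correlations, non-increasing, in [0, 1].
#' @slot ccaSummary list with mean, max, nAbove0.3, nAbove0.5, auc.
#' @slot nSubjectsUsed integer.
#'
#' @exportClass AlignmentReport
setClass("AlignmentReport",
  representation(ckaPos = "numeric", ckaNeg = "numeric", ccaRho = "numeric",
                 ccaSummary = "list", nSubjectsUsed = "integer"))
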