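#' Accessor generics
#'
#' Small accessor family for the package's containers: subject identifiers,
#' dosage matrices, SNP metadata, UDIP score matrices, QC masks,
#' explained-variance ratios and training loss traces.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname accessors
#' @export
setGeneric("udipValues", function(x) standardGeneric("udipValues"))

#' @rdname accessors
#' @export
setGeneric("qcMask", function(x) standardGeneric("qcMask"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' @rdname accessors
#' @export
setGeneric("latentFactors", function(x) standardGeneric("latentFactors"))

#' @rdname accessors
#' @export
setGeneric("minP", function(x) standardGeneric("minP"))

setMethod("subjectIds", "GenotypePanel", function(x) x@subjectIds)
setMethod("subjectIds", "LatentCohort", function(x) x@subjectIds)
setMethod("subjectIds", "PairedVolumeCohort", function(x) x@subjectIds)
setMethod("subjectIds", "TraitTable", function(x) x@subjectIds)
setMethod("subjectIds", "SyntheticCohort", function(x) x@genotypes@subjectIds)
setMethod("subjectIds", "EmbeddingTensor", function(x) x@subjectIds)
setMethod("subjectIds", "UdipMatrix", function(x) x@subjectIds)

setMethod("dosages", "GenotypePanel", function(x) x@dosages)
setMethod("dosages", "SyntheticCohort", function(x) x@genotypes@dosages)
setMethod("snpInfo", "GenotypePanel", function(x) x@snpInfo)
setMethod("snpInfo", "GwasSummary", function(x) x@snpInfo)
setMethod("udipValues", "UdipMatrix", function(x) x@udip)
setMethod("qcMask", "UdipMatrix", function(x) x@qcMask)
setMethod("explainedVariance", "UdipMatrix", function(x) x@explainedVariance)
setMethod("lossTrace", "ContrastiveState", function(x) x@lossTrace)
setMethod("latentFactors", "LatentCohort", function(x) x@z)
setMethod("latentFactors", "SyntheticCohort", function(x) x@latent@z)
setMethod("minP", "GwasSummary", function(x) x@minp)

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel: %d subjects x %d SNPs on %d chromosome(s)\n",
              nrow(object@dosages), ncol(object@dosages),
              length(unique(object@snpInfo$chrom))))
  cat(sprintf("  MAF range: %.4f - %.4f\n",
              min(object@snpInfo$maf), max(object@snpInfo$maf)))
})

setMethod("show", "PairedVolumeCohort", function(object) {
  cat(sprintf("PairedVolumeCohort: %d subjects, volumes %s (2 modalities)\n",
              length(object@subjectIds),
              paste(object@shape, collapse = "x")))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d subjects, %d SNPs (%d causal), %d latent dims,\n",
    length(subjectIds(object)), ncol(object@genotypes@dosages),
    length(object@latent@causalIdx), ncol(object@latent@z)))
  cat(sprintf("  volumes %s, %d traits\n",
              paste(object@volumes@shape, collapse = "x"),
              ncol(object@traits@idps)))
})

setMethod("show", "ContrastiveState", function(object) {
  cat(sprintf(
    "ContrastiveState: step %d, queues %d x %d, last loss %s\n",
    object@step, nrow(object@queueA), ncol(object@queueA),
    if (length(object@lossTrace))
      sprintf("%.4f", utils::tail(object@lossTrace, 1)) else "NA"))
})

setMethod("show", "UdipMatrix", function(object) {
  cat(sprintf(
    "UdipMatrix [%s]: %d subjects x %d UDIPs, %.1f%% variance explained, %d masked entries\n",
    object@modality, nrow(object@udip), ncol(object@udip),
    100 * sum(object@explainedVariance), sum(!object@qcMask)))
})

setMethod("show", "GwasSummary", function(object) {
  cat(sprintf("GwasSummary: %d SNPs x %d UDIPs; min(minP) = %.3g\n",
              nrow(object@p), ncol(object@p),
              if (length(object@minp)) min(object@minp) else NA))
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf(
    "OverlapResult: %d shared / %d total clusters (%.1f%% shared); unique A %d, unique B %d\n",
    object@shared, object@total, object@percentShared,
    object@uniqueA, object@uniqueB))
})

setMethod("show", "AlignmentReport", function(object) {
  cat(sprintf(
    "AlignmentReport (n = %d): CKA pos %.3f +/- %.3f, neg %.3f +/- %.3f\n",
    object@nSubjectsUsed,
    mean(object@ckaPos), stats::sd(object@ckaPos),
    mean(object@ckaNeg), stats::sd(object@ckaNeg)))
  s <- object@ccaSummary
  cat(sprintf("  CCA: mean %.3f, max %.3f, n(rho>0.3) %d, n(rho>0.5) %d\n",
              s$mean, s$max, s$nAbove0.3, s$nAbove0.5))
})
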