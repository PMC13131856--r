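#' Extract frozen-encoder patch embeddings for a cohort
#'
#' Applies the (trained, frozen) query encoder to every subject's volume of
#' the requested modality: tokenize, encode, no projection head. Purely
#' deterministic.
#'
#' @param queryParams encoder parameters (e.g.
#'   \code{trainContrastive(...)$queryParams}).
#' @param cohort a \code{\linkS4class{PairedVolumeCohort}}.
#' @param modality "a" or "b".
#' @param spec the \code{PatchSpec} the encoder was built with.
#' @param batchSize subjects per forward pass.
#' @return an \code{\linkS4class{EmbeddingTensor}}
#'   (subjects x patches x width).
#' @export
extractEmbeddings <- function(queryParams, cohort, modality = c("a", "b"),
                              spec, batchSize = 50L) {
  modality <- match.arg(modality)
  stopifnot(is(cohort, "PairedVolumeCohort"), is(spec, "PatchSpec"))
  vols <- if (modality == "a") cohort@volA else cohort@volB
  n <- length(cohort@subjectIds)
  P <- prod(gridDims(spec))
  w <- attr(queryParams, "width")
  values <- array(NA_real_, dim = c(n, P, w))
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    tok <- asTokenBatch(vols[, , , idx, drop = FALSE], spec)
    pe <- encForwardFast(queryParams, tok, length(idx),
                         project = FALSE)$patchEmb
    for (j in seq_along(idx))
      values[idx[j], , ] <- pe[((j - 1L) * P + 1L):(j * P), , drop = FALSE]
  }
  new("EmbeddingTensor", values = values, subjectIds = cohort@subjectIds,
      modality = modality)
}

# flatten subjects x patches x width to subjects x (patches * width),
# patch-major (feature index = (patch - 1) * width + w)
flattenEmbeddings <- function(emb) {
  # aperm to (n, width, patches); column-major matrix() then orders width
  # fastest within each patch block, i.e. patch-major features
  v <- aperm(emb@values, c(1L, 3L, 2L))
  matrix(v, nrow = dim(emb@values)[1])
}

#' Reduce patch embeddings to K latent imaging phenotypes by PCA
#'
#' Each subject's patches x width embedding matrix is flattened patch-major
#' into one feature vector. With \code{jointFit = TRUE} (default) a single
#' PCA basis is fitted on the stacked modality-a and modality-b rows
#' (column-mean-centered, no variance scaling) and both modalities are
#' projected with it, placing them in one coordinate system; with
#' \code{jointFit = FALSE} each modality is fitted separately.
#'
#' @param embA,embB \code{EmbeddingTensor}s for the two modalities.
#' @param k number of components (UDIPs) to retain.
#' @param jointFit logical, fit one basis on both modalities.
#' @return list with \code{a} and \code{b}, each a
#'   \code{\linkS4class{UdipMatrix}} (QC mask all-TRUE).
#' @export
pcaReduce <- function(embA, embB, k = 128L, jointFit = TRUE) {
  stopifnot(is(embA, "EmbeddingTensor"), is(embB, "EmbeddingTensor"))
  xa <- flattenEmbeddings(embA)
  xb <- flattenEmbeddings(embB)
  stopIfNot(ncol(xa) == ncol(xb), "modalities must share feature dimension")
  k <- as.integer(k)
  nTotal <- if (jointFit) nrow(xa) + nrow(xb) else min(nrow(xa), nrow(xb))
  stopIfNot(k >= 1L && k <= min(nTotal - 1L, ncol(xa)),
            "k must be <= min(total rows - 1, feature count)")
  mkUdip <- function(scores, evr, ids, modality) {
    colnames(scores) <- sprintf("UDIP_%d", seq_len(ncol(scores)) - 1L)
    new("UdipMatrix", subjectIds = ids, udip = scores,
        explainedVariance = evr,
        qcMask = matrix(TRUE, nrow(scores), ncol(scores)),
        modality = modality)
  }
  if (jointFit) {
    fit <- stats::prcomp(rbind(xa, xb), center = TRUE, scale. = FALSE,
                         rank. = k)
    evr <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)]
    project <- function(x) sweep(x, 2L, fit$center) %*% fit$rotation
    list(a = mkUdip(project(xa), evr, embA@subjectIds, embA@modality),
         b = mkUdip(project(xb), evr, embB@subjectIds, embB@modality))
  } else {
    one <- function(x, emb) {
      fit <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
      evr <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)]
      mkUdip(fit$x[, seq_len(k), drop = FALSE], evr, emb@subjectIds,
             emb@modality)
    }
    list(a = one(xa, embA), b = one(xb, embB))
  }
}

#' Per-entry outlier QC of a UDIP matrix
#'
#' For each UDIP column, entries deviating from the column mean by strictly
#' more than \code{zThresh} standard deviations are masked (per-entry, so
#' downstream per-UDIP sample sizes may differ). Statistics are computed
#' once on the unmasked values, making the operation idempotent.
#'
#' @param udips a \code{\linkS4class{UdipMatrix}}.
#' @param zThresh positive threshold in SD units (default 5).
#' @return the \code{UdipMatrix} with an updated \code{qcMask}.
#' @export
outlierMask <- function(udips, zThresh = 5) {
  stopifnot(is(udips, "UdipMatrix"))
  stopIfNot(zThresh > 0, "zThresh must be positive")
  x <- udips@udip
  mask <- matrix(TRUE, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    s <- stats::sd(x[, j])
    if (s == 0 || !is.finite(s)) {
      warning(sprintf("column %d has zero SD; no masking applied", j))
      next
    }
    mask[, j] <- abs(x[, j] - mean(x[, j])) <= zThresh * s
  }
  udips@qcMask <- mask
  udips
}
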