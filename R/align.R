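#' Linear centered kernel alignment (CKA)
#'
#' Feature-space form of linear CKA: with column-centered X and Y,
#' \deqn{CKA = \|Y^T X\|_F^2 / (\|X^T X\|_F \, \|Y^T Y\|_F)}
#' equal to the cosine similarity between the centered Gram matrices.
#' Invariant to orthogonal rotation, translation and positive rescaling of
#' either argument; always in [0, 1]. Rows must be paired by subject; rows
#' with missing values in either matrix are removed first.
#'
#' @param x,y numeric matrices with the same number of rows (n >= 2).
#' @return scalar in [0, 1].
#' @export
linearCKA <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopIfNot(nrow(x) == nrow(y), "x and y must have the same number of rows")
  keep <- stats::complete.cases(x) & stats::complete.cases(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  stopIfNot(nrow(x) >= 2L, "need at least 2 complete paired rows")
  xc <- sweep(x, 2L, colMeans(x))
  yc <- sweep(y, 2L, colMeans(y))
  nx <- sqrt(sum((crossprod(xc))^2))
  ny <- sqrt(sum((crossprod(yc))^2))
  if (nx == 0 || ny == 0)
    stop("zero-variance input: CKA undefined", call. = FALSE)
  sum((crossprod(yc, xc))^2) / (nx * ny)
}

# a permutation of 1..n with no fixed point, redrawn until none remain
drawDerangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Bootstrap / permutation CKA distributions for paired UDIPs
#'
#' Positive pairs: \code{nBoot} bootstrap resamples of matched subject rows,
#' CKA each. Negative pairs: \code{nBoot} random permutations of the
#' modality-b subject assignment (permutations containing any self-match are
#' redrawn, so no positive pair leaks into the null), CKA each.
#'
#' @param udipA,udipB \code{\linkS4class{UdipMatrix}} objects with matching
#'   subjects, or plain matrices with identical row counts.
#' @param nBoot number of resamples per distribution (>= 1).
#' @param seed integer RNG seed.
#' @return list with \code{pos}, \code{neg} (numeric vectors) and their
#'   means/sds.
#' @export
ckaBootstrap <- function(udipA, udipB, nBoot = 100L, seed = 1L) {
  m <- matchedPair(udipA, udipB)
  a <- m$a; b <- m$b
  keep <- stats::complete.cases(a) & stats::complete.cases(b)
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  n <- nrow(a)
  stopIfNot(n >= 3L, "need at least 3 matched subjects")
  stopIfNot(nBoot >= 1L, "nBoot must be >= 1")
  withSeed(seed, {
    pos <- vapply(seq_len(nBoot), function(i) {
      idx <- sample.int(n, replace = TRUE)
      linearCKA(a[idx, , drop = FALSE], b[idx, , drop = FALSE])
    }, numeric(1))
    neg <- vapply(seq_len(nBoot), function(i) {
      linearCKA(a, b[drawDerangement(n), , drop = FALSE])
    }, numeric(1))
  })
  list(pos = pos, neg = neg,
       posMean = mean(pos), posSd = stats::sd(pos),
       negMean = mean(neg), negSd = stats::sd(neg), n = n)
}

# UDIP values with masked entries set to NA
maskedValues <- function(udips) {
  v <- udips@udip
  v[!udips@qcMask] <- NA_real_
  v
}

# merge two UDIP matrices (or plain matrices) into row-aligned value blocks
matchedPair <- function(udipA, udipB) {
  a <- if (is(udipA, "UdipMatrix")) maskedValues(udipA) else as.matrix(udipA)
  b <- if (is(udipB, "UdipMatrix")) maskedValues(udipB) else as.matrix(udipB)
  if (is(udipA, "UdipMatrix") && is(udipB, "UdipMatrix")) {
    common <- intersect(udipA@subjectIds, udipB@subjectIds)
    a <- a[match(common, udipA@subjectIds), , drop = FALSE]
    b <- b[match(common, udipB@subjectIds), , drop = FALSE]
  }
  stopIfNot(nrow(a) == nrow(b), "subject rows must match")
  list(a = a, b = b)
}

#' Canonical correlation analysis of two feature blocks
#'
#' Columns are standardized to zero mean and unit variance, rows with
#' missing values removed, and canonical directions computed maximizing
#' successive cross-correlations under orthogonality. The number of
#' components is \code{min(n - 1, min(p, q))} (reduced with a warning under
#' rank deficiency). A warning is emitted when \code{n < 5 * max(p, q)}
#' because unregularized in-sample canonical correlations inflate.
#'
#' @param x,y numeric matrices with paired rows.
#' @return list with \code{rho} (non-increasing canonical correlations),
#'   \code{scoresX}, \code{scoresY} (per-subject canonical scores) and
#'   \code{nUsed}.
#' @export
ccaFit <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopIfNot(nrow(x) == nrow(y), "x and y must have the same number of rows")
  keep <- stats::complete.cases(x) & stats::complete.cases(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  stopIfNot(n >= 3L, "need at least 3 complete rows")
  if (n < 5 * max(p, q))
    warning("n < 5 * max(p, q): in-sample canonical correlations may inflate")
  xs <- standardizeCols(x)
  ys <- standardizeCols(y)
  nComp <- min(n - 1L, min(p, q))
  cc <- stats::cancor(xs, ys, xcenter = FALSE, ycenter = FALSE)
  got <- length(cc$cor)
  if (got < nComp)
    warning(sprintf("rank deficiency: %d components instead of %d",
                    got, nComp))
  nComp <- min(nComp, got)
  rho <- pmin(pmax(cc$cor[seq_len(nComp)], 0), 1)
  list(rho = rho,
       scoresX = xs %*% cc$xcoef[, seq_len(nComp), drop = FALSE],
       scoresY = ys %*% cc$ycoef[, seq_len(nComp), drop = FALSE],
       nUsed = n)
}

#' Summarize a canonical-correlation profile
#'
#' Mean, maximum, counts of components with rho strictly above 0.3 and 0.5,
#' and the normalized area under the sorted-correlation bar profile (equal
#' to the mean).
#'
#' @param rho non-empty numeric vector of canonical correlations.
#' @return list(mean, max, nAbove0.3, nAbove0.5, auc).
#' @export
ccaSummary <- function(rho) {
  stopIfNot(length(rho) >= 1L, "rho must be non-empty")
  list(mean = mean(rho), max = max(rho),
       nAbove0.3 = sum(rho > 0.3), nAbove0.5 = sum(rho > 0.5),
       auc = mean(sort(rho, decreasing = TRUE)))
}

#' Full cross-modal alignment report
#'
#' Combines the bootstrap/permutation CKA distributions and the CCA
#' canonical-correlation summary for a pair of UDIP matrices.
#'
#' @inheritParams ckaBootstrap
#' @return an \code{\linkS4class{AlignmentReport}}.
#' @export
alignmentReport <- function(udipA, udipB, nBoot = 100L, seed = 1L) {
  cka <- ckaBootstrap(udipA, udipB, nBoot = nBoot, seed = seed)
  m <- matchedPair(udipA, udipB)
  cca <- ccaFit(m$a, m$b)
  new("AlignmentReport", ckaPos = cka$pos, ckaNeg = cka$neg,
      ccaRho = sort(cca$rho, decreasing = TRUE),
      ccaSummary = ccaSummary(cca$rho), nSubjectsUsed = as.integer(cca$nUsed))
}
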