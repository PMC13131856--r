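#' @importFrom GenomicRanges GRanges reduce findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
NULL

coerceCovariates <- function(covariates, ids) {
  if (is.null(covariates))
    return(list(mat = matrix(1, length(ids), 1L), ids = ids))
  if (is(covariates, "TraitTable")) {
    cid <- covariates@subjectIds
    covariates <- covariates@covariates
  } else if (!is.null(covariates$IID)) {
    cid <- as.character(covariates$IID)
    covariates <- covariates[setdiff(names(covariates), "IID")]
  } else if (!is.null(rownames(covariates)) &&
             !is.integer(attr(covariates, "row.names"))) {
    cid <- rownames(covariates)
  } else {
    stopIfNot(nrow(covariates) == length(ids),
              "covariates need IIDs or one row per subject")
    cid <- ids
  }
  mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  list(mat = mm, ids = cid)
}

# drop collinear columns (keeps the first of each dependent group)
dropCollinear <- function(m, warnPrefix = "covariates") {
  qr0 <- qr(m)
  if (qr0$rank < ncol(m)) {
    keep <- qr0$pivot[seq_len(qr0$rank)]
    dropped <- colnames(m)[setdiff(seq_len(ncol(m)), keep)]
    warning(sprintf("%s: dropping collinear column(s) %s", warnPrefix,
                    paste(dropped, collapse = ", ")))
    m <- m[, sort(keep), drop = FALSE]
  }
  m
}

#' Per-SNP, per-UDIP OLS association scan
#'
#' For every retained SNP (realized MAF >= \code{mafMin}) and every UDIP
#' column: phenotype and dosage are residualized on the covariates (with
#' intercept), then the simple regression of the residuals is computed
#' (numerically identical to the SNP coefficient in the full multiple
#' regression, by Frisch-Waugh); two-sided p-values use the t distribution
#' with n - c - 2 degrees of freedom (c = number of covariate columns).
#' Masked UDIP entries are excluded per phenotype, so per-UDIP sample sizes
#' differ. SNPs with constant dosage in a phenotype's analysis rows are
#' skipped (NA statistics) with a warning.
#'
#' An OLS scan is appropriate here because the synthetic subjects are
#' unrelated (Hardy-Weinberg draws, no population structure); no mixed-model
#' random effect is needed.
#'
#' @param panel a \code{\linkS4class{GenotypePanel}}.
#' @param udips a \code{\linkS4class{UdipMatrix}}.
#' @param covariates NULL, a data.frame (with IID column, rownames, or
#'   one row per panel subject), or a \code{TraitTable}.
#' @param mafMin minor-allele-frequency threshold (default 0.01).
#' @return a \code{\linkS4class{GwasSummary}}.
#' @export
gwasScan <- function(panel, udips, covariates = NULL, mafMin = 0.01) {
  stopifnot(is(panel, "GenotypePanel"), is(udips, "UdipMatrix"))
  keepSnp <- which(panel@snpInfo$maf >= mafMin)
  info <- panel@snpInfo[keepSnp, , drop = FALSE]
  G0 <- panel@dosages[, keepSnp, drop = FALSE]

  cov <- coerceCovariates(covariates, panel@subjectIds)
  ids <- intersect(intersect(panel@subjectIds, udips@subjectIds), cov$ids)
  stopIfNot(length(ids) >= 4L, "too few subjects shared across inputs")
  G0 <- G0[match(ids, panel@subjectIds), , drop = FALSE]
  U <- udips@udip[match(ids, udips@subjectIds), , drop = FALSE]
  M <- udips@qcMask[match(ids, udips@subjectIds), , drop = FALSE]
  C0 <- cov$mat[match(ids, cov$ids), , drop = FALSE]
  C0 <- dropCollinear(C0)

  nSnp <- ncol(G0); nU <- ncol(U)
  dims <- list(info$snpId, colnames(U))
  beta <- se <- tst <- pv <- matrix(NA_real_, nSnp, nU, dimnames = dims)
  nUsed <- matrix(0L, nSnp, nU, dimnames = dims)
  warnedConst <- FALSE
  for (j in seq_len(nU)) {
    rows <- which(M[, j] & stats::complete.cases(C0))
    n <- length(rows)
    dfree <- n - ncol(C0) - 1L
    if (dfree < 1L) next
    Cq <- qr.Q(qr(C0[rows, , drop = FALSE]))
    y <- U[rows, j]
    yr <- y - Cq %*% crossprod(Cq, y)
    Gr <- G0[rows, , drop = FALSE]
    Gr <- Gr - Cq %*% crossprod(Cq, Gr)
    sxx <- colSums(Gr * Gr)
    poly <- sxx > 1e-12 &
      colNonConstant(G0[rows, , drop = FALSE])
    if (any(!poly) && !warnedConst) {
      warning(sprintf("%d SNP(s) constant within analysis rows; skipped",
                      sum(!poly)))
      warnedConst <- TRUE
    }
    b <- as.numeric(crossprod(Gr, yr)) / sxx
    rss <- sum(yr * yr) - b^2 * sxx
    rss[rss < 0] <- 0
    s <- sqrt(rss / dfree / sxx)
    b[!poly] <- NA; s[!poly] <- NA
    tv <- b / s
    p <- 2 * stats::pt(-abs(tv), df = dfree)
    p <- pmax(p, 1e-300)
    beta[, j] <- b; se[, j] <- s; tst[, j] <- tv; pv[, j] <- p
    nUsed[, j] <- n
  }
  agg <- minpRows(pv)
  new("GwasSummary", beta = beta, se = se, tstat = tst, p = pv,
      nUsed = nUsed, minp = agg$minp, bestUdip = agg$best,
      snpInfo = info, udipNames = colnames(U))
}

colNonConstant <- function(g) {
  rng <- apply(g, 2L, function(x) max(x) - min(x))
  rng > 0
}

minpRows <- function(p) {
  minp <- suppressWarnings(apply(p, 1L, min, na.rm = TRUE))
  minp[!is.finite(minp)] <- NA_real_
  best <- apply(p, 1L, function(r)
    if (all(is.na(r))) NA_integer_ else which.min(r))
  list(minp = minp, best = as.integer(best))
}

#' Per-SNP minP aggregation across UDIPs
#'
#' The per-SNP summary statistic is the minimum association p-value over the
#' UDIP axis; ties are broken by the lowest UDIP index.
#'
#' @param summary a \code{\linkS4class{GwasSummary}} or a p-value matrix
#'   (SNPs x UDIPs).
#' @return list with \code{minp} and \code{bestUdip}.
#' @export
minpAggregate <- function(summary) {
  p <- if (is(summary, "GwasSummary")) summary@p else as.matrix(summary)
  agg <- minpRows(p)
  list(minp = agg$minp, bestUdip = agg$best)
}

#' Squared dosage correlation between two SNPs
#'
#' @param panel a \code{GenotypePanel}.
#' @param snpI,snpJ column indices or SNP ids.
#' @return r-squared in [0, 1] (symmetric; allele flips give identical
#'   values).
#' @export
ldR2 <- function(panel, snpI, snpJ) {
  ix <- if (is.character(snpI)) match(snpI, panel@snpInfo$snpId) else snpI
  jx <- if (is.character(snpJ)) match(snpJ, panel@snpInfo$snpId) else snpJ
  gi <- panel@dosages[, ix]; gj <- panel@dosages[, jx]
  if (stats::sd(gi) == 0 || stats::sd(gj) == 0)
    stop("monomorphic SNP: r2 undefined", call. = FALSE)
  stats::cor(gi, gj)^2
}

#' Clump significant SNPs into non-overlapping genomic loci
#'
#' Greedy lead-SNP clumping: significant SNPs (minP < alpha) are sorted by
#' ascending minP (ties by ascending position, then SNP id); the best
#' remaining SNP becomes a lead, and every remaining significant
#' same-chromosome SNP with dosage r-squared > \code{r2Max} to the lead is
#' assigned to its locus, whose interval spans the member positions.
#' Finally, same-chromosome loci separated by less than \code{mergeKb} kb
#' are merged, the merged lead being the member with smallest minP. Every
#' significant SNP belongs to exactly one locus, and merged loci do not
#' overlap within a chromosome.
#'
#' @param summary a \code{\linkS4class{GwasSummary}}.
#' @param panel the \code{GenotypePanel} the scan was run on (for LD).
#' @param alpha significance threshold (default 5e-8 / 128).
#' @param r2Max LD independence threshold (default 0.1).
#' @param mergeKb physical-proximity merge distance in kb (default 250).
#' @return a \code{GRanges} locus set (possibly empty) with mcols
#'   \code{leadSnp}, \code{topP}, \code{nSnps}, \code{members}
#'   (comma-separated SNP ids), 1-based inclusive coordinates.
#' @export
clumpLoci <- function(summary, panel, alpha = 5e-8 / 128, r2Max = 0.1,
                      mergeKb = 250) {
  stopifnot(is(summary, "GwasSummary"))
  info <- summary@snpInfo
  sig <- which(!is.na(summary@minp) & summary@minp < alpha)
  if (!length(sig)) return(emptyLocusSet())
  ord <- sig[order(summary@minp[sig], info$pos[sig], info$snpId[sig])]
  colIdx <- match(info$snpId, panel@snpInfo$snpId)
  loci <- list()
  remaining <- ord
  while (length(remaining)) {
    lead <- remaining[1L]
    sameChr <- remaining[info$chrom[remaining] == info$chrom[lead]]
    gLead <- panel@dosages[, colIdx[lead]]
    r2 <- vapply(sameChr, function(s) {
      g <- panel@dosages[, colIdx[s]]
      if (stats::sd(g) == 0 || stats::sd(gLead) == 0) return(0)
      stats::cor(gLead, g)^2
    }, numeric(1))
    members <- unique(c(lead, sameChr[r2 > r2Max]))
    loci[[length(loci) + 1L]] <- list(
      chrom = info$chrom[lead],
      start = min(info$pos[members]), end = max(info$pos[members]),
      lead = info$snpId[lead], topP = summary@minp[lead],
      members = info$snpId[members])
    remaining <- setdiff(remaining, members)
  }
  # merge same-chromosome loci closer than mergeKb
  df <- data.frame(chrom = vapply(loci, `[[`, "", "chrom"),
                   start = vapply(loci, `[[`, 0, "start"),
                   end = vapply(loci, `[[`, 0, "end"),
                   stringsAsFactors = FALSE)
  o <- order(df$chrom, df$start, df$end)
  loci <- loci[o]; df <- df[o, ]
  merged <- list()
  i <- 1L
  while (i <= length(loci)) {
    cur <- loci[[i]]
    j <- i + 1L
    while (j <= length(loci) && loci[[j]]$chrom == cur$chrom &&
           (loci[[j]]$start - cur$end) < mergeKb * 1000) {
      nxt <- loci[[j]]
      better <- nxt$topP < cur$topP
      cur <- list(chrom = cur$chrom, start = min(cur$start, nxt$start),
                  end = max(cur$end, nxt$end),
                  lead = if (better) nxt$lead else cur$lead,
                  topP = min(cur$topP, nxt$topP),
                  members = c(cur$members, nxt$members))
      j <- j + 1L
    }
    merged[[length(merged) + 1L]] <- cur
    i <- j
  }
  gr <- GRanges(
    seqnames = vapply(merged, `[[`, "", "chrom"),
    ranges = IRanges(start = vapply(merged, `[[`, 0, "start"),
                     end = vapply(merged, `[[`, 0, "end")))
  mcols(gr)$leadSnp <- vapply(merged, `[[`, "", "lead")
  mcols(gr)$topP <- vapply(merged, `[[`, 0, "topP")
  mcols(gr)$nSnps <- vapply(merged, function(x) length(x$members), 0L)
  mcols(gr)$members <- vapply(merged, function(x)
    paste(x$members, collapse = ","), "")
  sort(gr)
}

emptyLocusSet <- function() {
  gr <- GRanges()
  mcols(gr)$leadSnp <- character(0)
  mcols(gr)$topP <- numeric(0)
  mcols(gr)$nSnps <- integer(0)
  mcols(gr)$members <- character(0)
  gr
}

#' Construct a locus set from coordinates
#'
#' Convenience constructor for a locus \code{GRanges} (1-based inclusive).
#'
#' @param chrom,start,end vectors of equal length.
#' @param leadSnp,topP optional annotations.
#' @return a \code{GRanges} with the package's locus mcols.
#' @export
locusSet <- function(chrom, start, end, leadSnp = NULL, topP = NULL) {
  stopIfNot(all(start <= end), "loci must satisfy start <= end")
  gr <- GRanges(seqnames = chrom, ranges = IRanges(start = start, end = end))
  n <- length(gr)
  mcols(gr)$leadSnp <- if (is.null(leadSnp)) rep(NA_character_, n) else leadSnp
  mcols(gr)$topP <- if (is.null(topP)) rep(NA_real_, n) else topP
  mcols(gr)$nSnps <- rep(NA_integer_, n)
  mcols(gr)$members <- rep(NA_character_, n)
  gr
}

extendLoci <- function(gr, padKb) {
  if (!length(gr)) return(gr)
  s <- pmax(1L, GenomicRanges::start(gr) - as.integer(padKb * 1000))
  e <- GenomicRanges::end(gr) + as.integer(padKb * 1000)
  GRanges(seqnames = GenomicRanges::seqnames(gr),
          ranges = IRanges(start = s, end = e))
}

#' Cross-set locus overlap via padded interval clustering
#'
#' Every locus is extended by \code{padKb} kb on both sides (floored at
#' position 1); extended loci from both sets are union-clustered by
#' transitive interval intersection per chromosome (interval-index based).
#' A cluster containing members of both sets is shared. The partition
#' identity shared + uniqueA + uniqueB = total holds on every input;
#' \code{percentShared = 100 * shared / total} (0 when both sets are empty).
#'
#' @param setA,setB locus \code{GRanges} (from \code{\link{clumpLoci}} or
#'   \code{\link{locusSet}}).
#' @param padKb extension pad in kb (default 125).
#' @return an \code{\linkS4class{OverlapResult}}; per-locus cluster
#'   assignments are in \code{mcols(result@clusters)} and in the
#'   \code{lociA}/\code{lociB} attributes.
#' @export
overlapLoci <- function(setA, setB, padKb = 125) {
  extA <- extendLoci(setA, padKb)
  extB <- extendLoci(setB, padKb)
  # rebuild on shared seqlevels so sets touching different chromosomes
  # combine cleanly
  allExt <- GRanges(
    seqnames = c(as.character(GenomicRanges::seqnames(extA)),
                 as.character(GenomicRanges::seqnames(extB))),
    ranges = IRanges(start = c(GenomicRanges::start(extA),
                               GenomicRanges::start(extB)),
                     end = c(GenomicRanges::end(extA),
                             GenomicRanges::end(extB))))
  src <- rep(c("A", "B"), c(length(extA), length(extB)))
  if (!length(allExt)) {
    res <- new("OverlapResult", shared = 0L, uniqueA = 0L, uniqueB = 0L,
               total = 0L, percentShared = 0, clusters = GRanges())
    return(res)
  }
  clusters <- reduce(allExt, min.gapwidth = 0L)
  hit <- findOverlaps(allExt, clusters)
  cl <- integer(length(allExt))
  cl[queryHits(hit)] <- subjectHits(hit)
  hasA <- tabulate(cl[src == "A"], nbins = length(clusters)) > 0
  hasB <- tabulate(cl[src == "B"], nbins = length(clusters)) > 0
  shared <- sum(hasA & hasB)
  uniqueA <- sum(hasA & !hasB)
  uniqueB <- sum(!hasA & hasB)
  total <- length(clusters)
  mcols(clusters)$hasA <- hasA
  mcols(clusters)$hasB <- hasB
  mcols(clusters)$shared <- hasA & hasB
  res <- new("OverlapResult", shared = as.integer(shared),
             uniqueA = as.integer(uniqueA), uniqueB = as.integer(uniqueB),
             total = as.integer(total),
             percentShared = if (total == 0) 0 else 100 * shared / total,
             clusters = clusters)
  attr(res, "lociA") <- cl[src == "A"]
  attr(res, "lociB") <- cl[src == "B"]
  res
}

#' Overlap partition arithmetic
#'
#' Builds an \code{\linkS4class{OverlapResult}} directly from cluster
#' counts, enforcing the partition identity
#' shared + uniqueA + uniqueB = total.
#'
#' @param shared,uniqueA,uniqueB non-negative integer cluster counts.
#' @return an \code{OverlapResult}.
#' @examples
#' overlapPartition(23, 14, 7)   # 44 total, 52.3% shared
#' overlapPartition(17, 0, 8)    # 25 total
#' @export
overlapPartition <- function(shared, uniqueA, uniqueB) {
  total <- as.integer(shared + uniqueA + uniqueB)
  new("OverlapResult", shared = as.integer(shared),
      uniqueA = as.integer(uniqueA), uniqueB = as.integer(uniqueB),
      total = total,
      percentShared = if (total == 0) 0 else 100 * shared / total,
      clusters = GRanges())
}

#' Loci novel with respect to reference locus sets
#'
#' Returns the target loci whose padded interval intersects no padded locus
#' of any reference set (same pad convention as \code{\link{overlapLoci}}).
#'
#' @param setTarget locus \code{GRanges}.
#' @param referenceSets a list of locus \code{GRanges} (or a single one).
#' @param padKb pad in kb (default 125).
#' @return the novel subset of \code{setTarget}.
#' @export
novelLoci <- function(setTarget, referenceSets, padKb = 125) {
  if (is(referenceSets, "GRanges")) referenceSets <- list(referenceSets)
  extT <- extendLoci(setTarget, padKb)
  if (!length(extT)) return(setTarget)
  hitAny <- rep(FALSE, length(extT))
  for (ref in referenceSets) {
    extR <- extendLoci(ref, padKb)
    if (length(extR))
      hitAny <- hitAny |
        suppressWarnings(GenomicRanges::countOverlaps(extT, extR) > 0)
  }
  setTarget[!hitAny]
}
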