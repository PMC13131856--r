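#' Phenome-wide UDIP-trait association scan
#'
#' For every (UDIP, trait) pair fits the linear regression
#' \code{trait ~ udip + covariates} and records the two-sided p-value and
#' coefficient of the UDIP term. Masked UDIP entries are dropped pairwise
#' (per-pair sample sizes reported). The Bonferroni threshold is
#' \code{0.05 / nUdips / nTraits}, computed from the actual matrix
#' dimensions. P-values are floored at 1e-300.
#'
#' @param udips a \code{\linkS4class{UdipMatrix}} or numeric matrix.
#' @param traits a \code{\linkS4class{TraitTable}} or numeric matrix.
#' @param covariates NULL or a data.frame/matrix (row-aligned, or with IID
#'   column / rownames); collinear columns are dropped with a warning.
#' @return list with \code{p}, \code{beta}, \code{se} (udips x traits
#'   matrices), \code{n}, \code{bonferroniAlpha} and \code{nSignificant}.
#' @export
phewasScan <- function(udips, traits, covariates = NULL) {
  uIds <- if (is(udips, "UdipMatrix")) udips@subjectIds else
    rownames(udips) %||% as.character(seq_len(nrow(udips)))
  U <- if (is(udips, "UdipMatrix")) maskedValues(udips) else as.matrix(udips)
  if (is(traits, "TraitTable")) {
    tIds <- traits@subjectIds
    if (is.null(covariates))
      covariates <- cbind(data.frame(IID = tIds), traits@covariates)
    Tm <- traits@idps
  } else {
    Tm <- as.matrix(traits)
    tIds <- rownames(Tm) %||% as.character(seq_len(nrow(Tm)))
  }
  cov <- coerceCovariates(covariates, uIds)
  ids <- Reduce(intersect, list(uIds, tIds, cov$ids))
  stopIfNot(length(ids) >= 4L, "too few subjects shared across inputs")
  U <- U[match(ids, uIds), , drop = FALSE]
  Tm <- Tm[match(ids, tIds), , drop = FALSE]
  C0 <- dropCollinear(cov$mat[match(ids, cov$ids), , drop = FALSE])

  nU <- ncol(U); nT <- ncol(Tm)
  dn <- list(colnames(U) %||% sprintf("UDIP_%d", seq_len(nU) - 1L),
             colnames(Tm) %||% sprintf("TRAIT_%d", seq_len(nT)))
  p <- beta <- se <- matrix(NA_real_, nU, nT, dimnames = dn)
  nMat <- matrix(0L, nU, nT, dimnames = dn)
  for (i in seq_len(nU)) {
    rows0 <- which(!is.na(U[, i]))
    for (j in seq_len(nT)) {
      rows <- rows0[!is.na(Tm[rows0, j])]
      n <- length(rows)
      X <- cbind(udip = U[rows, i], C0[rows, , drop = FALSE])
      dfree <- n - ncol(X)
      if (dfree < 1L) next
      fit <- stats::lm.fit(X, Tm[rows, j])
      rss <- sum(fit$residuals^2)
      xtxInv <- chol2inv(chol(crossprod(X)))
      s <- sqrt(rss / dfree * xtxInv[1L, 1L])
      tv <- fit$coefficients[1L] / s
      p[i, j] <- max(2 * stats::pt(-abs(tv), dfree), 1e-300)
      beta[i, j] <- fit$coefficients[1L]
      se[i, j] <- s
      nMat[i, j] <- n
    }
  }
  alpha <- 0.05 / nU / nT
  list(p = p, beta = beta, se = se, n = nMat, bonferroniAlpha = alpha,
       nSignificant = sum(p < alpha, na.rm = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Incremental R-squared of a UDIP block beyond covariates
#'
#' Fits the reduced model (covariates only, with intercept) and the full
#' model (covariates + all K UDIP columns) by OLS and reports
#' \code{deltaR2 = R2_full - R2_reduced} with the partial (omnibus) F-test
#' \deqn{F = \frac{(RSS_{red} - RSS_{full}) / K}{RSS_{full} / (n - c - K - 1)}}
#' and its p-value from F(K, n - c - K - 1).
#'
#' @param trait numeric response vector.
#' @param udips numeric matrix of K UDIP columns (K >= 1).
#' @param covariates NULL or row-aligned covariate data.frame/matrix.
#' @return list(r2Cov, r2Full, deltaR2, F, df1, df2, p, n).
#' @export
incrementalR2 <- function(trait, udips, covariates = NULL) {
  udips <- as.matrix(udips)
  K <- ncol(udips)
  if (K == 0L)
    stop("no UDIP columns: incremental R2 undefined", call. = FALSE)
  n0 <- length(trait)
  C0 <- if (is.null(covariates)) matrix(1, n0, 1L) else
    dropCollinear(stats::model.matrix(~ ., as.data.frame(covariates)))
  keep <- stats::complete.cases(trait, udips, C0)
  y <- trait[keep]
  Xr <- C0[keep, , drop = FALSE]
  Xf <- cbind(Xr, udips[keep, , drop = FALSE])
  n <- length(y)
  c <- ncol(Xr) - 1L
  stopIfNot(n > c + K + 1L, "need n > c + K + 1")
  if (qr(Xf)$rank < ncol(Xf))
    stop("singular full design (collinear UDIP/covariate columns)",
         call. = FALSE)
  tss <- sum((y - mean(y))^2)
  rssR <- sum(stats::lm.fit(Xr, y)$residuals^2)
  rssF <- sum(stats::lm.fit(Xf, y)$residuals^2)
  df2 <- n - c - K - 1L
  Fstat <- ((rssR - rssF) / K) / (rssF / df2)
  list(r2Cov = 1 - rssR / tss, r2Full = 1 - rssF / tss,
       deltaR2 = (rssR - rssF) / tss, F = Fstat, df1 = K, df2 = df2,
       p = stats::pf(Fstat, K, df2, lower.tail = FALSE), n = n)
}

#' Trait-association summaries for CCA components
#'
#' For each canonical component, regresses every trait on the component
#' score (plus covariates), collects the -log10 p-values of the score term
#' over traits and reports the requested percentile of that distribution
#' (the strong-association tail; \code{percentile = 100} gives the maximum).
#'
#' @param ccaScores numeric matrix of per-subject canonical scores
#'   (components in columns), e.g. \code{ccaFit(...)$scoresX}.
#' @param traits a \code{TraitTable} or numeric matrix.
#' @param covariates NULL or covariates as in \code{\link{phewasScan}}.
#' @param percentile percentile of the -log10 p distribution (default 95).
#' @return data.frame with component index, the percentile summary, and the
#'   number of traits used.
#' @export
ccaComponentAssoc <- function(ccaScores, traits, covariates = NULL,
                              percentile = 95) {
  ccaScores <- as.matrix(ccaScores)
  if (is(traits, "TraitTable")) {
    if (is.null(covariates)) covariates <- traits@covariates
    traits <- traits@idps
  }
  traits <- as.matrix(traits)
  stopIfNot(nrow(ccaScores) == nrow(traits),
            "scores and traits must be row-aligned")
  if (ncol(traits) < 20L)
    warning("fewer than 20 traits: the percentile summary is unstable")
  res <- phewasScan(ccaScores, traits, covariates)
  nlp <- -log10(res$p)
  summ <- apply(nlp, 1L, function(v)
    stats::quantile(v, probs = percentile / 100, na.rm = TRUE,
                    names = FALSE))
  data.frame(component = seq_len(ncol(ccaScores)),
             logpPercentile = as.numeric(summ),
             nTraits = ncol(traits))
}
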