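#' Write and read paired volume cohorts as NIfTI-1
#'
#' One file per subject per modality, named \code{<iid>_<modality>.nii.gz}.
#' Data arrays and affines round-trip losslessly.
#'
#' @param cohort a \code{\linkS4class{PairedVolumeCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeVolumes <- function(cohort, dir) {
  stopifnot(is(cohort, "PairedVolumeCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(cohort@subjectIds)) {
    iid <- cohort@subjectIds[i]
    for (mod in c("a", "b")) {
      v <- if (mod == "a") cohort@volA[, , , i] else cohort@volB[, , , i]
      p <- file.path(dir, sprintf("%s_%s.nii.gz", iid, mod))
      RNifti::writeNifti(RNifti::asNifti(v), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' @rdname writeVolumes
#' @param subjectIds subjects to read; default: all IIDs found in \code{dir}.
#' @param strict if TRUE, a subject missing either modality is an error;
#'   otherwise the subject is dropped with a warning.
#' @export
readVolumes <- function(dir, subjectIds = NULL, strict = FALSE) {
  files <- list.files(dir, pattern = "_[ab]\\.nii(\\.gz)?$")
  iids <- unique(sub("_[ab]\\.nii(\\.gz)?$", "", files))
  if (!is.null(subjectIds)) iids <- subjectIds
  stopIfNot(length(iids) > 0, "no paired NIfTI volumes found")
  pathOf <- function(iid, mod) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", iid, mod))
    if (!file.exists(p)) p <- file.path(dir, sprintf("%s_%s.nii", iid, mod))
    p
  }
  complete <- vapply(iids, function(iid)
    file.exists(pathOf(iid, "a")) && file.exists(pathOf(iid, "b")),
    logical(1))
  if (any(!complete)) {
    msg <- sprintf("subject(s) missing a modality file: %s",
                   paste(iids[!complete], collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; dropped")
    iids <- iids[complete]
  }
  stopIfNot(length(iids) > 0, "no complete subject pairs")
  first <- as.array(RNifti::readNifti(pathOf(iids[1], "a")))
  shape <- dim(first)
  volA <- array(NA_real_, dim = c(shape, length(iids)))
  volB <- array(NA_real_, dim = c(shape, length(iids)))
  for (i in seq_along(iids)) {
    volA[, , , i] <- as.array(RNifti::readNifti(pathOf(iids[i], "a")))
    volB[, , , i] <- as.array(RNifti::readNifti(pathOf(iids[i], "b")))
  }
  new("PairedVolumeCohort", subjectIds = as.character(iids), volA = volA,
      volB = volB, shape = as.integer(shape))
}

#' Write / read a UDIP matrix as CSV
#'
#' Header \code{IID,UDIP_0,...,UDIP_{K-1}}, one row per subject, masked
#' entries written as empty fields; a JSON sidecar (\code{<path>.json})
#' stores the explained-variance ratios and modality tag.
#'
#' @param udips a \code{\linkS4class{UdipMatrix}}.
#' @param path CSV output path.
#' @return invisibly, \code{path}.
#' @export
writeUdipCsv <- function(udips, path) {
  stopifnot(is(udips, "UdipMatrix"))
  v <- maskedValues(udips)
  df <- data.frame(IID = udips@subjectIds, v, check.names = FALSE)
  colnames(df) <- c("IID", sprintf("UDIP_%d", seq_len(ncol(v)) - 1L))
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  jsonlite::write_json(
    list(modality = udips@modality,
         explainedVarianceRatio = udips@explainedVariance,
         nSubjects = nrow(v), k = ncol(v)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeUdipCsv
#' @export
readUdipCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopIfNot(colnames(df)[1] == "IID", "first column must be IID")
  m <- as.matrix(df[, -1, drop = FALSE])
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list(modality = "a", explainedVarianceRatio = rep(NA_real_, ncol(m)))
  new("UdipMatrix", subjectIds = as.character(df$IID), udip = ifelse(is.na(m), 0, m),
      explainedVariance = as.numeric(meta$explainedVarianceRatio),
      qcMask = !is.na(m), modality = meta$modality %||% "a")
}

#' Export association summary statistics
#'
#' Writes one TSV per UDIP with fastGWA-style columns
#' (CHR, SNP, POS, A1, A2, N, BETA, SE, P) and a MINP file
#' (CHR, SNP, POS, MINP, BEST_UDIP).
#'
#' @param summary a \code{\linkS4class{GwasSummary}}.
#' @param prefix output path prefix; files are
#'   \code{<prefix>.<udip>.tsv} and \code{<prefix>.minp.tsv}.
#' @return invisibly, the written paths.
#' @export
writeGwasTsv <- function(summary, prefix) {
  stopifnot(is(summary, "GwasSummary"))
  info <- summary@snpInfo
  paths <- character(0)
  for (j in seq_along(summary@udipNames)) {
    df <- data.frame(CHR = info$chrom, SNP = info$snpId, POS = info$pos,
                     A1 = info$A1, A2 = info$A2, N = summary@nUsed[, j],
                     BETA = summary@beta[, j], SE = summary@se[, j],
                     P = summary@p[, j])
    p <- sprintf("%s.%s.tsv", prefix, summary@udipNames[j])
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  dfm <- data.frame(CHR = info$chrom, SNP = info$snpId, POS = info$pos,
                    MINP = summary@minp, BEST_UDIP = summary@bestUdip)
  pm <- sprintf("%s.minp.tsv", prefix)
  utils::write.table(dfm, pm, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, pm))
}

#' Export loci as BED (plus JSON sidecar)
#'
#' Internal coordinates are 1-based inclusive; the BED export converts to
#' 0-based half-open. Lead SNP, top p and members go into
#' \code{<path>.json}.
#'
#' @param loci a locus \code{GRanges}.
#' @param path BED output path.
#' @return invisibly, \code{path}.
#' @export
writeLociBed <- function(loci, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(loci)),
                   start = GenomicRanges::start(loci) - 1L,
                   end = GenomicRanges::end(loci),
                   name = mcols(loci)$leadSnp)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    lapply(seq_along(loci), function(i) list(
      chrom = as.character(GenomicRanges::seqnames(loci))[i],
      start = GenomicRanges::start(loci)[i],
      end = GenomicRanges::end(loci)[i],
      leadSnp = mcols(loci)$leadSnp[i],
      topP = mcols(loci)$topP[i],
      members = strsplit(mcols(loci)$members[i] %||% "", ",")[[1]])),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a genotype panel as dosage TSV + SNP map (and optional VCF)
#'
#' The dosage matrix is written tab-separated with an IID first column; the
#' SNP map follows the .bim convention (chrom, snpId, pos, A1, A2).
#'
#' @param panel a \code{GenotypePanel}.
#' @param prefix output prefix; writes \code{<prefix>.dosage.tsv} and
#'   \code{<prefix>.map.tsv}, plus \code{<prefix>.vcf} when
#'   \code{vcf = TRUE}.
#' @param vcf also write a minimal VCF 4.2 with GT genotypes.
#' @return invisibly, the written paths.
#' @export
writeGenotypes <- function(panel, prefix, vcf = FALSE) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- as.data.frame(panel@dosages)
  colnames(d) <- panel@snpInfo$snpId
  d <- cbind(IID = panel@subjectIds, d)
  p1 <- paste0(prefix, ".dosage.tsv")
  utils::write.table(d, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- data.frame(chrom = panel@snpInfo$chrom, snpId = panel@snpInfo$snpId,
                  pos = panel@snpInfo$pos, A1 = panel@snpInfo$A1,
                  A2 = panel@snpInfo$A2)
  p2 <- paste0(prefix, ".map.tsv")
  utils::write.table(m, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(p1, p2)
  if (vcf) {
    p3 <- paste0(prefix, ".vcf")
    gt <- c("0/0", "0/1", "1/1")
    con <- file(p3, "w")
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", panel@subjectIds),
                       collapse = "\t")), con)
    for (s in seq_len(ncol(panel@dosages))) {
      writeLines(paste(c(panel@snpInfo$chrom[s], panel@snpInfo$pos[s],
                         panel@snpInfo$snpId[s], panel@snpInfo$A2[s],
                         panel@snpInfo$A1[s], ".", "PASS", ".", "GT",
                         gt[panel@dosages[, s] + 1L]), collapse = "\t"), con)
    }
    close(con)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Export a trait table as CSV (IID first column)
#'
#' @param traits a \code{TraitTable}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTraitCsv <- function(traits, path) {
  stopifnot(is(traits, "TraitTable"))
  df <- cbind(data.frame(IID = traits@subjectIds),
              as.data.frame(traits@idps), traits@covariates)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
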