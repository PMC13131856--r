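#' Full-scale reference parameter profile
#'
#' Returns the full-scale reference configuration as a named list: encoder
#' of 12 layers / 6 heads / width 384 / 256-dim projection; temperature
#' 0.07, momentum 0.999, queue 65,536, lr 1e-4, cosine warm restarts
#' (T0=10, Tmult=2, etaMin=1e-6), 300 epochs; 14x16x14 patches on volumes
#' padded to 182x224x182 (2,366 patches); 128 UDIPs; 5-SD outlier QC; GWAS
#' alpha 5e-8/128, clumping r2 0.1 / 250 kb, overlap pad 125 kb. This
#' profile documents the reference configuration; it is far beyond desktop
#' scale and is not run by the package's tests.
#'
#' @return named list of configuration objects and scalars.
#' @export
fullScaleProfile <- function() {
  list(encCfg = encoderConfig(),
       conCfg = contrastiveConfig(),
       spec = patchSpec(c(14L, 16L, 14L), c(182L, 224L, 182L)),
       kUdip = 128L, zThresh = 5, alpha = 5e-8 / 128, r2Max = 0.1,
       mergeKb = 250, padKb = 125)
}

#' Run the full desk-scale pipeline
#'
#' Executes the stages in order: simulate -> train -> embed -> reduce/QC ->
#' align -> gwas/minP/clump (per modality) -> overlap -> phewas, honoring
#' the stage toggles, and optionally writes all artifacts plus a manifest
#' to \code{outDir}. Fully reproducible given \code{seed}.
#'
#' @param seed master seed; spawns sub-streams for every stochastic stage.
#' @param cohortArgs list of overrides for \code{\link{simulateCohort}}.
#' @param encCfg,conCfg encoder / training configurations (desk defaults).
#' @param kUdip number of UDIPs (PCA components).
#' @param zThresh outlier-QC threshold in SDs.
#' @param alpha,r2Max,mergeKb,padKb genetics-stage parameters.
#' @param nBoot CKA bootstrap/permutation resamples.
#' @param stages character vector of stages to run (prefix order is always
#'   respected; later stages require earlier ones).
#' @param outDir optional artifact directory.
#' @param queryParams optional pre-trained encoder parameters; when supplied
#'   (with \code{spec}) the train stage is skipped and embedding uses them.
#' @param spec optional \code{PatchSpec} accompanying \code{queryParams}.
#' @return named list with the per-stage results (cohort, training, udips,
#'   align, gwas, loci, overlap, phewas, manifest).
#' @export
runPipeline <- function(seed = 1L, cohortArgs = list(),
                        encCfg = deskEncoderConfig(),
                        conCfg = deskContrastiveConfig(seed = seed),
                        kUdip = 16L, zThresh = 5, alpha = 5e-8 / 128,
                        r2Max = 0.1, mergeKb = 250, padKb = 125,
                        nBoot = 50L,
                        stages = c("simulate", "train", "embed", "align",
                                   "gwas", "overlap", "phewas"),
                        outDir = NULL, queryParams = NULL, spec = NULL) {
  t0 <- Sys.time()
  out <- list(seed = seed)
  logStage <- function(stage, expr) {
    tic <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(difftime(Sys.time(), tic, units = "secs"))))
    res
  }

  cohort <- logStage("simulate",
    do.call(simulateCohort, utils::modifyList(list(seed = seed), cohortArgs)))
  out$cohort <- cohort

  if ("train" %in% stages && is.null(queryParams)) {
    training <- logStage("train",
      trainContrastive(cohort@volumes, encCfg, conCfg, spec = spec))
    queryParams <- training$queryParams
    spec <- training$spec
    out$training <- training
  } else if (is.null(queryParams)) {
    # untrained encoder still defines a deterministic embedding
    if (is.null(spec)) spec <- patchSpec(c(8L, 8L, 8L), cohort@volumes@shape)
    queryParams <- initEncoderParams(encCfg, spec, seed = conCfg@seed)
  } else if (is.null(spec)) {
    stop("queryParams supplied without their PatchSpec", call. = FALSE)
  }

  if (any(c("embed", "align", "gwas", "overlap", "phewas") %in% stages)) {
    emb <- logStage("embed", {
      ea <- extractEmbeddings(queryParams, cohort@volumes, "a", spec)
      eb <- extractEmbeddings(queryParams, cohort@volumes, "b", spec)
      red <- pcaReduce(ea, eb, k = kUdip, jointFit = TRUE)
      list(a = outlierMask(red$a, zThresh), b = outlierMask(red$b, zThresh))
    })
    out$udips <- emb
  }

  if ("align" %in% stages)
    out$align <- logStage("align",
      alignmentReport(out$udips$a, out$udips$b, nBoot = nBoot,
                      seed = subSeed(seed, "align")))

  if (any(c("gwas", "overlap") %in% stages)) {
    out$gwas <- logStage("gwas", list(
      a = gwasScan(cohort@genotypes, out$udips$a, cohort@traits),
      b = gwasScan(cohort@genotypes, out$udips$b, cohort@traits)))
    out$loci <- logStage("clump", list(
      a = clumpLoci(out$gwas$a, cohort@genotypes, alpha, r2Max, mergeKb),
      b = clumpLoci(out$gwas$b, cohort@genotypes, alpha, r2Max, mergeKb)))
  }

  if ("overlap" %in% stages)
    out$overlap <- logStage("overlap",
      overlapLoci(out$loci$a, out$loci$b, padKb = padKb))

  if ("phewas" %in% stages)
    out$phewas <- logStage("phewas",
      phewasScan(out$udips$a, cohort@traits))

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    files <- character(0)
    if (!is.null(out$udips)) {
      files <- c(files,
        writeUdipCsv(out$udips$a, file.path(outDir, "udip_a.csv")),
        writeUdipCsv(out$udips$b, file.path(outDir, "udip_b.csv")))
    }
    if (!is.null(out$gwas))
      files <- c(files,
        writeGwasTsv(out$gwas$a, file.path(outDir, "gwas_a")),
        writeGwasTsv(out$gwas$b, file.path(outDir, "gwas_b")))
    if (!is.null(out$loci))
      files <- c(files,
        writeLociBed(out$loci$a, file.path(outDir, "loci_a.bed")),
        writeLociBed(out$loci$b, file.path(outDir, "loci_b.bed")))
    allFiles <- list.files(outDir, full.names = TRUE, recursive = TRUE)
    allFiles <- allFiles[!grepl("manifest\\.json$", allFiles)]
    manifest <- list(
      package = as.character(utils::packageVersion("UDIPalign")),
      rVersion = R.version.string,
      seed = seed, stages = stages,
      config = list(kUdip = kUdip, zThresh = zThresh, alpha = alpha,
                    r2Max = r2Max, mergeKb = mergeKb, padKb = padKb,
                    temperature = conCfg@temperature,
                    momentum = conCfg@momentum,
                    queueSize = conCfg@queueSize, epochs = conCfg@epochs),
      wallSeconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      files = lapply(stats::setNames(allFiles, basename(allFiles)),
                     function(f) unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$manifest <- manifest
  }
  out
}
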