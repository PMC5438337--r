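.stage <- function(name, expr, log) {
  log(paste0("stage ", name, ": start"))
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  log(paste0("stage ", name, ": done"))
  out
}

#' Cross-check genotype, cross-list and phenotype consistency
#'
#' Non-fatal validation mirroring the realities of breeding data: hybrids
#' whose parents lack genotypes are reported as dropped from prediction
#' but kept in the trial analysis; duplicated hybrid ids and phenotyped
#' hybrids absent from the cross list are flagged.
#'
#' @param parents a [GenotypeMatrix-class].
#' @param crosses cross list (hybridId, femaleId, maleId).
#' @param records plot records (or NULL).
#' @return list with \code{drops} (data.frame hybridId, reason),
#'   \code{duplicatedHybrids}, \code{nPredictable}.
#' @export
validateInputs <- function(parents, crosses, records = NULL) {
  genotyped <- lineIds(parents)
  bad <- !(crosses$femaleId %in% genotyped) |
    !(crosses$maleId %in% genotyped)
  drops <- data.frame(hybridId = as.character(crosses$hybridId[bad]),
                      reason = rep("parent not genotyped; dropped from prediction, kept in trial model",
                                   sum(bad)),
                      stringsAsFactors = FALSE)
  dup <- unique(crosses$hybridId[duplicated(crosses$hybridId)])
  orphans <- character()
  if (!is.null(records)) {
    hy <- unique(records$genotypeId[records$type == "hybrid"])
    orphans <- setdiff(hy, crosses$hybridId)
  }
  list(drops = drops, duplicatedHybrids = dup,
       phenotypedWithoutCross = orphans,
       nPredictable = sum(!bad))
}

#' Run the full heterotic-pattern discovery pipeline
#'
#' Executes the three-step approach end to end: (1) predict the
#' performance of all possible single crosses from trial BLUEs and
#' genome-wide marker effects, (2) identify heterotic patterns on the
#' predicted full matrix by simulated annealing over a range of group
#' sizes, (3) evaluate the patterns' short- and long-term success. Data
#' are either simulated (\code{cfg$sim}) or read from CSV paths
#' (\code{cfg$paths}). Every intermediate artifact is written to
#' \code{outDir} together with a structured log and a checksum manifest;
#' re-running with the same configuration and seed reproduces all
#' numeric outputs bit-identically.
#'
#' @param cfg list with fields: \code{sim} (a [simConfig()]) or
#'   \code{paths} (list genotypes, map, meta, crosses, plots);
#'   \code{mafMin} (QC threshold, default 0.05); \code{sizes} (group
#'   sizes for the sweep, default 2:10); \code{cvRuns} (chess-board CV
#'   runs, 0 to skip, default 0); \code{comparisonK} (crosses in the pool
#'   comparison, default 256 capped to the factorial); \code{seed}
#'   (master seed, default taken from \code{sim}).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the main results (vc, blues, effects,
#'   diallel, sweep, success, paths of artifacts).
#' @export
runPipeline <- function(cfg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "log.txt")
  cat("", file = logPath)
  log <- function(msg) cat(msg, "\n", file = logPath, append = TRUE,
                           sep = "")
  if (is.null(cfg$mafMin)) cfg$mafMin <- 0.05
  if (is.null(cfg$sizes)) cfg$sizes <- 2:10
  if (is.null(cfg$cvRuns)) cfg$cvRuns <- 0
  if (is.null(cfg$seed))
    cfg$seed <- if (!is.null(cfg$sim)) cfg$sim$seed else 1
  cfgOut <- cfg
  if (!is.null(cfgOut$sim)) cfgOut$sim <- unclass(cfgOut$sim)
  jsonlite::write_json(cfgOut, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  dat <- if (!is.null(cfg$sim)) {
    .stage("simulate", {
      prog <- simulateProgram(cfg$sim)
      list(parents = prog$parents, crosses = prog$crosses,
           plots = prog$plots, truth = prog$truth)
    }, log)
  } else {
    .stage("genomics", {
      p <- cfg$paths
      list(parents = readGenotypesCsv(p$genotypes, p$map, p$meta),
           crosses = readCrossList(p$crosses),
           plots = readPlotRecords(p$plots), truth = NULL)
    }, log)
  }

  qc <- .stage("genomics", {
    g <- filterMarkers(dat$parents, cfg$mafMin)
    list(parents = g, rd = rogersDistance(g))
  }, log)
  A <- additiveRelationship(qc$rd)
  writeMatrixCsv(qc$rd, file.path(outDir, "rogers_distance.csv"))

  val <- .stage("validate", validateInputs(qc$parents, dat$crosses,
                                           dat$plots), log)
  jsonlite::write_json(val, file.path(outDir, "validation.json"),
                       auto_unbox = TRUE, digits = NA)

  trial <- .stage("trial", {
    fit <- fitTrialModel(dat$plots)
    dec <- decomposeGcaSca(dat$plots)
    blues <- computeBlues(dat$plots)
    h2 <- heritability(fit$vc)
    ch <- commercialHeterosis(blues)
    list(vc = fit$vc, vcDecomposed = dec$vc, blues = blues, h2 = h2,
         heterosis = ch)
  }, log)
  write.csv(trial$blues, file.path(outDir, "blues.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(trial = as.list(trial$vc@sigma2),
         decomposed = as.list(trial$vcDecomposed@sigma2),
         h2 = trial$h2,
         commercialHeterosisBest = trial$heterosis$best),
    file.path(outDir, "variance_components.json"),
    auto_unbox = TRUE, digits = NA)

  pred <- .stage("prediction", {
    keep <- dat$crosses$femaleId %in% lineIds(qc$parents) &
      dat$crosses$maleId %in% lineIds(qc$parents)
    cr <- dat$crosses[keep, , drop = FALSE]
    hb <- trial$blues[trial$blues$type == "hybrid", ]
    y <- setNames(hb$blue, hb$genotypeId)
    cr <- cr[cr$hybridId %in% names(y), , drop = FALSE]
    codes <- codeHybrids(qc$parents, cr)
    eff <- fitRRBLUP(codes, y[cr$hybridId])
    H <- fullDiallel(eff, qc$parents, mode = "all")
    cv <- NULL
    if (cfg$cvRuns > 0)
      cv <- chessboardCV(codes, y[cr$hybridId], nRuns = cfg$cvRuns,
                         seed = cfg$seed + 101)
    list(effects = eff, H = H, cv = cv, codes = codes)
  }, log)
  writeMatrixCsv(pred$H, file.path(outDir, "diallel.csv"))
  if (!is.null(pred$cv))
    write.csv(pred$cv$results, file.path(outDir, "cv_abilities.csv"),
              row.names = FALSE)

  search <- .stage("search", {
    sizes <- cfg$sizes[2 * cfg$sizes <= nLines(qc$parents)]
    if (!length(sizes)) stop("no feasible group size for ",
                             nLines(qc$parents), " parents")
    sizeSweep(pred$H, sizes = sizes, seed = cfg$seed + 211,
              poolLabels = pools(qc$parents))
  }, log)
  jsonlite::write_json(
    lapply(search$patterns, function(p)
      list(size = p@size, score = p@score, group1 = p@group1,
           group2 = p@group2)),
    file.path(outDir, "patterns.json"), auto_unbox = TRUE, digits = NA)
  write.csv(search$stability, file.path(outDir, "stability.csv"),
            row.names = FALSE)

  success <- .stage("success", {
    pl <- pools(qc$parents)
    buildSuccessReport(pred$effects, pred$H, A, search, qc$parents,
                       femaleIds = names(pl)[pl == "female"],
                       maleIds = names(pl)[pl == "male"],
                       k = cfg$comparisonK %||% 256)
  }, log)
  write.csv(success$perSize, file.path(outDir, "success.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(plateau = success$plateau, comparison = success$comparison),
    file.path(outDir, "success.json"), auto_unbox = TRUE, digits = NA)

  arts <- setdiff(list.files(outDir), c("log.txt", "manifest.json"))
  sums <- tools::md5sum(file.path(outDir, sort(arts)))
  names(sums) <- sort(arts)
  jsonlite::write_json(as.list(sums), file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  log("pipeline complete")
  invisible(list(vc = trial$vc, vcDecomposed = trial$vcDecomposed,
                 h2 = trial$h2, blues = trial$blues,
                 heterosis = trial$heterosis,
                 effects = pred$effects, diallel = pred$H, cv = pred$cv,
                 sweep = search, success = success,
                 validation = val, outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
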