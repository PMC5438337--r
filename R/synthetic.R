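## Seed hygiene: run expr under a fixed seed, restoring the caller's RNG
## state afterwards so simulation stages are independently reproducible.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Configuration of a synthetic hybrid breeding program
#'
#' Defines the statistical structure of the generated program: two
#' parental pools whose divergence follows a Balding-Nichols model, an
#' unbalanced factorial of single crosses, an additive + dominance genetic
#' architecture, and augmented multi-location yield trials (replicated
#' checks, unreplicated entries).
#'
#' Defaults emulate a medium-grain hybrid rice segment: an unbalanced
#' factorial of 234 crosses among 48 restorer (male) and 8 maintainer
#' (female) lines (about 61 percent of the possible factorial), grown at
#' two locations, with genotype-by-location and error variances of the
#' magnitude observed in such trials (in (Mg/ha)^2). The genetic variance
#' targets are calibrated so the realized GCA (about 0.40) and SCA (about
#' 0.13) variances over the full factorial match those magnitudes; note
#' the dominance covariate carries additive margins, so only part of
#' \code{varDominance} becomes true SCA variance.
#'
#' @param nMale,nFemale pool sizes.
#' @param nHybrids number of single crosses to phenotype.
#' @param nMarkers,nChromosomes SNP panel size and genome structure.
#' @param poolDivergence Fst-like divergence of the two pools in [0, 1).
#' @param nQtl markers with non-zero effects.
#' @param varAdditive,varDominance target genetic variances among all
#'   possible hybrids ((Mg/ha)^2).
#' @param mu overall mean grain yield (Mg/ha).
#' @param nLocations,nChecks,blockSize,blocksPerTrial trial layout; each
#'   block holds \code{blockSize - nChecks} unreplicated entries plus every
#'   check once.
#' @param varLocation,varTrial,varBlock,varGxL,varError non-genetic
#'   variance components of the trial model.
#' @param maturityEffects fixed effects of the three maturity classes.
#' @param hybridsPerMaleShape gamma shape controlling how unbalanced the
#'   factorial is (small = more unbalanced).
#' @param checkMeanOffset,checkSd mean deviation and spread of the inbred
#'   check varieties relative to the hybrid mean.
#' @param seed master seed; fixes every downstream draw.
#' @return a list of class \code{SimulationConfig}.
#' @export
simConfig <- function(nMale = 48, nFemale = 8, nHybrids = 234,
                      nMarkers = 500, nChromosomes = 12,
                      poolDivergence = 0.3, nQtl = NULL,
                      varAdditive = 0.17, varDominance = 0.36,
                      mu = 5,
                      nLocations = 2, nChecks = 5, blockSize = 25,
                      blocksPerTrial = 4,
                      varLocation = 0.5, varTrial = 0.2, varBlock = 0.1,
                      varGxL = 2.10, varError = 0.97,
                      maturityEffects = c(-0.3, 0, 0.3),
                      hybridsPerMaleShape = 1,
                      checkMeanOffset = -1, checkSd = 0.2,
                      seed = 1) {
  if (is.null(nQtl)) nQtl <- min(100L, nMarkers)
  cfg <- as.list(environment())
  stopifnot(nMale > 0, nFemale > 0, nHybrids > 0, nMarkers > 0,
            nChromosomes > 0, nQtl > 0, nQtl <= nMarkers,
            poolDivergence >= 0, poolDivergence < 1,
            varAdditive >= 0, varDominance >= 0,
            varLocation >= 0, varTrial >= 0, varBlock >= 0,
            varGxL >= 0, varError >= 0,
            nLocations >= 1, nChecks >= 1, blockSize >= 2)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate divergent parental pools
#'
#' Per marker, an ancestral allele frequency p is drawn Uniform(0.1, 0.9);
#' pool-specific frequencies follow a Balding-Nichols Beta distribution
#' with variance p(1-p) * poolDivergence (poolDivergence = 0 gives one
#' panmictic pool). Lines are fully homozygous: dosage 2 with the pool
#' frequency. Markers are spread evenly over chromosomes with uniform
#' 1-based bp positions.
#'
#' @param cfg a [simConfig()] object.
#' @return a [GenotypeMatrix-class] with pool labels male/female.
#' @export
simulateParents <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  withSeed(cfg$seed + 11, {
    m <- cfg$nMarkers
    pAnc <- runif(m, 0.1, 0.9)
    F <- cfg$poolDivergence
    drawPool <- function() {
      if (F <= 0) return(pAnc)
      rbeta_ <- stats::rbeta
      rbeta_(m, pAnc * (1 - F) / F, (1 - pAnc) * (1 - F) / F)
    }
    pM <- drawPool()
    pF <- drawPool()
    dM <- matrix(2 * rbinom(cfg$nMale * m, 1, rep(pM, each = cfg$nMale)),
                 nrow = cfg$nMale)
    dF <- matrix(2 * rbinom(cfg$nFemale * m, 1, rep(pF, each = cfg$nFemale)),
                 nrow = cfg$nFemale)
    d <- rbind(dM, dF)
    rownames(d) <- c(sprintf("M%03d", seq_len(cfg$nMale)),
                     sprintf("F%03d", seq_len(cfg$nFemale)))
    chrom <- rep(seq_len(cfg$nChromosomes), length.out = m)
    chrom <- sort(chrom)
    pos <- numeric(m)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(4e7, length(idx)))
    }
    GenotypeMatrix(d,
                   pool = c(rep("male", cfg$nMale), rep("female", cfg$nFemale)),
                   segment = "SIM", chrom = chrom, pos = pos,
                   markerIds = sprintf("snp%05d", seq_len(m)))
  })
}

#' Simulate an unbalanced factorial cross list
#'
#' Crosses are sampled without replacement from the female x male grid
#' with per-male usage weights drawn from a gamma distribution, creating
#' the unbalanced factorial typical of commercial programs (some males
#' parent many hybrids, others few).
#'
#' @param cfg a [simConfig()] object.
#' @param parents parental [GenotypeMatrix-class] (from [simulateParents()]).
#' @return data.frame with columns hybridId, femaleId, maleId; no
#'   duplicate crosses.
#' @export
simulateCrosses <- function(cfg, parents) {
  pl <- pools(parents)
  females <- names(pl)[pl == "female"]
  males <- names(pl)[pl == "male"]
  total <- length(females) * length(males)
  if (cfg$nHybrids > total)
    stop("requested ", cfg$nHybrids, " hybrids but only ", total,
         " crosses are possible")
  withSeed(cfg$seed + 23, {
    grid <- expand.grid(femaleId = females, maleId = males,
                        stringsAsFactors = FALSE)
    w <- rgamma(length(males), shape = cfg$hybridsPerMaleShape) + 1e-3
    pick <- sample.int(nrow(grid), cfg$nHybrids,
                       prob = w[match(grid$maleId, males)])
    cr <- grid[sort(pick), , drop = FALSE]
    data.frame(hybridId = paste(cr$femaleId, cr$maleId, sep = "x"),
               femaleId = cr$femaleId, maleId = cr$maleId,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate the genetic architecture (ground truth)
#'
#' A random subset of nQtl markers receives additive and dominance effects
#' drawn from normal distributions and rescaled so that the realized
#' additive and dominance variances among all possible single crosses hit
#' the configured targets exactly; the remaining markers have zero effect.
#'
#' @param cfg a [simConfig()] object.
#' @param parents parental [GenotypeMatrix-class].
#' @return a list of class \code{TruthSet}: per-marker effects \code{a},
#'   \code{d}, intercept \code{mu}, QTL indices, the full female x male
#'   matrix of true hybrid genotypic values, and realized second-degree
#'   statistics (additive, dominance, total, GCA/SCA decomposition over
#'   the complete factorial).
#' @export
simulateEffects <- function(cfg, parents) {
  pl <- pools(parents)
  females <- names(pl)[pl == "female"]
  males <- names(pl)[pl == "male"]
  d <- dosage(parents)
  m <- ncol(d)
  withSeed(cfg$seed + 37, {
    qtl <- sort(sample.int(m, cfg$nQtl))
    a <- numeric(m); dd <- numeric(m)
    a[qtl] <- rnorm(cfg$nQtl)
    dd[qtl] <- rnorm(cfg$nQtl)
    pF <- d[females, qtl, drop = FALSE] / 2
    pM <- d[males, qtl, drop = FALSE] / 2
    nF <- length(females); nM <- length(males)
    ## all-pairs covariates at QTL: arrays (nF*nM) x nQtl
    zA <- matrix(0, nF * nM, cfg$nQtl)
    zD <- matrix(0, nF * nM, cfg$nQtl)
    for (j in seq_len(cfg$nQtl)) {
      zA[, j] <- as.vector(outer(pF[, j], pM[, j], `+`)) - 1
      zD[, j] <- as.vector(outer(pF[, j], pM[, j],
                                 function(f, mm) f * (1 - mm) + (1 - f) * mm))
    }
    gA <- as.vector(zA %*% a[qtl])
    gD <- as.vector(zD %*% dd[qtl])
    vA <- var(gA); vD <- var(gD)
    if (cfg$varAdditive == 0 || vA == 0) a[] <- 0
    else a <- a * sqrt(cfg$varAdditive / vA)
    if (cfg$varDominance == 0 || vD == 0) dd[] <- 0
    else dd <- dd * sqrt(cfg$varDominance / vD)
    values <- matrix(cfg$mu + as.vector(zA %*% a[qtl]) +
                       as.vector(zD %*% dd[qtl]),
                     nrow = nF, ncol = nM, dimnames = list(females, males))
    gf <- rowMeans(values) - mean(values)
    gm <- colMeans(values) - mean(values)
    sca <- values - outer(rowMeans(values), colMeans(values), `+`) +
      mean(values)
    truth <- list(
      a = setNames(a, colnames(d)), d = setNames(dd, colnames(d)),
      mu = cfg$mu, qtl = qtl, values = values,
      realized = c(
        additive = if (any(a != 0)) cfg$varAdditive else 0,
        dominance = if (any(dd != 0)) cfg$varDominance else 0,
        total = var(as.vector(values)),
        gcaFemale = var(gf), gcaMale = var(gm),
        sca = var(as.vector(sca))))
    class(truth) <- "TruthSet"
    truth
  })
}

#' Simulate augmented multi-location yield trials
#'
#' Every location evaluates each hybrid exactly once (unreplicated
#' entries); entries are randomized into blocks of
#' \code{blockSize - nChecks} entries, every block additionally carries
#' each of the \code{nChecks} replicated check varieties once, and blocks
#' are grouped into trials. Plot yield is
#' mu + maturity + genotypic value + location + trial + block + GxL + error
#' with all random terms drawn at the configured variances.
#'
#' @param cfg a [simConfig()] object.
#' @param crosses cross list from [simulateCrosses()].
#' @param truth a TruthSet from [simulateEffects()].
#' @return data.frame of plot records (genotypeId, type, femaleId, maleId,
#'   locationId, trialId, blockId, maturityClass, yield) with an
#'   \code{"effects"} attribute holding the drawn random effects and the
#'   per-genotype true values (for parameter-recovery diagnostics).
#' @export
simulateTrials <- function(cfg, crosses, truth) {
  entriesPerBlock <- cfg$blockSize - cfg$nChecks
  if (entriesPerBlock < 1)
    stop("blockSize (", cfg$blockSize, ") must exceed nChecks (",
         cfg$nChecks, ")")
  withSeed(cfg$seed + 53, {
    hyb <- crosses$hybridId
    gval <- setNames(truth$values[cbind(crosses$femaleId, crosses$maleId)],
                     hyb)
    checkIds <- sprintf("CHK%02d", seq_len(cfg$nChecks))
    checkVal <- setNames(truth$mu + cfg$checkMeanOffset +
                           rnorm(cfg$nChecks, 0, cfg$checkSd), checkIds)
    genos <- c(hyb, checkIds)
    matClass <- setNames(sample.int(length(cfg$maturityEffects),
                                    length(genos), replace = TRUE), genos)
    locs <- sprintf("LOC%d", seq_len(cfg$nLocations))
    locEff <- setNames(rnorm(cfg$nLocations, 0, sqrt(cfg$varLocation)), locs)
    gxl <- matrix(rnorm(length(genos) * cfg$nLocations, 0, sqrt(cfg$varGxL)),
                  nrow = length(genos), dimnames = list(genos, locs))
    rows <- vector("list", cfg$nLocations)
    trialEff <- list(); blockEff <- list()
    for (k in seq_along(locs)) {
      ord <- sample(hyb)
      nBlocks <- ceiling(length(ord) / entriesPerBlock)
      blockOf <- rep(seq_len(nBlocks), each = entriesPerBlock)[
        seq_along(ord)]
      nTrials <- ceiling(nBlocks / cfg$blocksPerTrial)
      trialOfBlock <- rep(seq_len(nTrials), each = cfg$blocksPerTrial)[
        seq_len(nBlocks)]
      tEff <- setNames(rnorm(nTrials, 0, sqrt(cfg$varTrial)),
                       sprintf("T%d", seq_len(nTrials)))
      bEff <- setNames(rnorm(nBlocks, 0, sqrt(cfg$varBlock)),
                       sprintf("T%d.B%d", trialOfBlock, seq_len(nBlocks)))
      trialEff[[locs[k]]] <- tEff
      blockEff[[locs[k]]] <- bEff
      ## entry plots + one plot per check per block
      gb <- data.frame(genotypeId = ord, block = blockOf,
                       stringsAsFactors = FALSE)
      cb <- expand.grid(genotypeId = checkIds, block = seq_len(nBlocks),
                        stringsAsFactors = FALSE)
      pl <- rbind(gb, cb)
      pl$type <- ifelse(pl$genotypeId %in% checkIds, "check", "hybrid")
      pl$trial <- trialOfBlock[pl$block]
      pl$trialId <- sprintf("T%d", pl$trial)
      pl$blockId <- sprintf("T%d.B%d", pl$trial, pl$block)
      pl$locationId <- locs[k]
      g <- pl$genotypeId
      base <- ifelse(pl$type == "hybrid", gval[g], checkVal[g])
      pl$yield <- base +
        cfg$maturityEffects[matClass[g]] +
        locEff[locs[k]] + tEff[pl$trialId] + bEff[pl$blockId] +
        gxl[cbind(g, locs[k])] +
        rnorm(nrow(pl), 0, sqrt(cfg$varError))
      pl$maturityClass <- paste0("mat", matClass[g])
      rows[[k]] <- pl
    }
    out <- do.call(rbind, rows)
    idx <- match(out$genotypeId, crosses$hybridId)
    out$femaleId <- crosses$femaleId[idx]
    out$maleId <- crosses$maleId[idx]
    out <- out[, c("genotypeId", "type", "femaleId", "maleId", "locationId",
                   "trialId", "blockId", "maturityClass", "yield")]
    rownames(out) <- NULL
    attr(out, "effects") <- list(
      genotypeValue = c(gval, checkVal), location = locEff,
      trial = trialEff, block = blockEff, gxl = gxl,
      maturityClass = matClass, checkIds = checkIds)
    out
  })
}

#' Simulate a complete breeding program
#'
#' Runs [simulateParents()], [simulateCrosses()], [simulateEffects()] and
#' [simulateTrials()] under the master seed; one seed reproduces the whole
#' program bit-identically.
#'
#' @param cfg a [simConfig()] object.
#' @return list with elements config, parents, crosses, truth, plots.
#' @export
simulateProgram <- function(cfg) {
  parents <- simulateParents(cfg)
  crosses <- simulateCrosses(cfg, parents)
  truth <- simulateEffects(cfg, parents)
  plots <- simulateTrials(cfg, crosses, truth)
  list(config = cfg, parents = parents, crosses = crosses, truth = truth,
       plots = plots)
}
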