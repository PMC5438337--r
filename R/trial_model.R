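## --- internal helpers -----------------------------------------------------

.checkRecords <- function(records) {
  need <- c("genotypeId", "type", "locationId", "trialId", "blockId",
            "maturityClass", "yield")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("plot records lack columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$yield))) stop("non-finite yield values")
  ## block labels must nest in trials: within a location, one block label
  ## may not span two trials
  key <- paste(records$locationId, records$blockId)
  tr <- tapply(records$trialId, key, function(z) length(unique(z)))
  if (any(tr > 1))
    stop("non-nested block labels: a block spans several trials within ",
         "a location")
  invisible(records)
}

## random-effect terms, dropping factors with a single level
.reFormula <- function(records, base = NULL,
                       genoTerm = "(1 | genotypeId)", extra = character()) {
  if (is.null(base))
    base <- if (length(unique(records$maturityClass)) > 1)
      "yield ~ maturityClass" else "yield ~ 1"
  terms <- genoTerm
  if (length(unique(records$locationId)) > 1)
    terms <- c(terms, "(1 | locationId)")
  if (length(unique(paste(records$locationId, records$trialId))) > 1)
    terms <- c(terms, "(1 | locationId:trialId)")
  if (length(unique(paste(records$locationId, records$blockId))) >
      length(unique(paste(records$locationId, records$trialId))))
    terms <- c(terms, "(1 | locationId:trialId:blockId)")
  terms <- c(terms, extra)
  as.formula(paste(base, "+", paste(terms, collapse = " + ")))
}

.lmerCtrl <- function() {
  lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.rankZ = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    calc.derivs = FALSE)
}

.vcFromFit <- function(fit, map, records, model) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  est <- setNames(vc$vcov, vc$grp)
  out <- setNames(numeric(length(map)), names(map))
  for (nm in names(map)) out[nm] <- if (map[nm] %in% names(est))
    est[[map[nm]]] else 0
  out["error"] <- est[["Residual"]]
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  new("VarianceComponents", sigma2 = out,
      nLocations = length(unique(records$locationId)),
      nReplicates = 1L,
      logLik = as.numeric(logLik(fit)),
      converged = conv,
      boundary = names(out)[out < 1e-8],
      model = model)
}

.checkMaturity <- function(records) {
  if (length(unique(records$maturityClass)) < 2) return(invisible())
  X <- stats::model.matrix(~maturityClass, records)
  if (qr(X)$rank < ncol(X)) {
    stop("singular fixed design: aliased maturity classes among ",
         paste(unique(records$maturityClass), collapse = ", "))
  }
}

## --- exported operations --------------------------------------------------

#' Fit the augmented-trial mixed model
#'
#' REML fit of
#' \deqn{y = \mu + maturity + genotype + location + trial(location) +
#'   block(trial) + genotype \times location + \epsilon}
#' with fixed intercept and maturity class and all remaining terms random.
#' Unreplicated entries are admissible because the replicated checks
#' identify the residual variance within locations; genotype-by-location
#' then separates from error. Requires at least two locations.
#'
#' @param records plot-record data.frame (see [simulateTrials()] for the
#'   column contract).
#' @return list with \code{vc} (a [VarianceComponents-class]),
#'   \code{blups} (genotype BLUPs), and \code{fit} (the underlying
#'   \code{merMod}, e.g. for likelihood-ratio tests).
#' @export
fitTrialModel <- function(records) {
  .checkRecords(records)
  if (length(unique(records$locationId)) < 2)
    stop("at least 2 locations are required to separate GxL from error")
  .checkMaturity(records)
  records$maturityClass <- factor(records$maturityClass)
  ## degenerate noiseless data: genotype means explain every plot exactly.
  ## The REML surface is singular there (the genotype/error variance ratio
  ## diverges), so the components are evaluated analytically instead.
  gm <- tapply(records$yield, records$genotypeId, mean)
  if (max(abs(records$yield - gm[records$genotypeId])) <
      1e-10 * max(1, sd(records$yield))) {
    gv <- as.numeric(gm)
    if (nlevels(records$maturityClass) > 1) {
      mat <- tapply(as.character(records$maturityClass),
                    records$genotypeId, `[`, 1)
      gv <- stats::residuals(stats::lm(gv ~ factor(mat))) + mean(gv)
    }
    s2 <- c(genotype = var(gv), location = 0, trial = 0, block = 0,
            gxl = 0, error = 0)
    vc <- new("VarianceComponents", sigma2 = s2,
              nLocations = length(unique(records$locationId)),
              nReplicates = 1L, logLik = Inf, converged = TRUE,
              boundary = names(s2)[s2 < 1e-8], model = "trial (noiseless)")
    blups <- data.frame(genotypeId = names(gm),
                        blup = as.numeric(gm) - mean(gm),
                        stringsAsFactors = FALSE, row.names = NULL)
    return(list(vc = vc, blups = blups, fit = NULL))
  }
  form <- .reFormula(records, extra = "(1 | genotypeId:locationId)")
  fit <- lme4::lmer(form, data = records, REML = TRUE, control = .lmerCtrl())
  map <- c(genotype = "genotypeId", location = "locationId",
           trial = "locationId:trialId",
           block = "locationId:trialId:blockId",
           gxl = "genotypeId:locationId", error = "Residual")
  vc <- .vcFromFit(fit, map, records, "trial")
  re <- lme4::ranef(fit)$genotypeId
  blups <- data.frame(genotypeId = rownames(re), blup = re[[1]],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(vc = vc, blups = blups, fit = fit)
}

#' Decompose genetic variance into GCA and SCA components
#'
#' Refits the trial model replacing the hybrid genotype effect with random
#' female GCA, male GCA and SCA (female-by-male) effects plus their three
#' interactions with location. Check varieties keep their own genotypic
#' term (the GCA/SCA structure applies to hybrids only, via indicator
#' weighting). By construction the decomposed genetic variance is
#' sigma2_gca_female + sigma2_gca_male + sigma2_sca.
#'
#' @param records plot records; hybrid rows must carry femaleId/maleId.
#' @param includeSca set FALSE to fit the reduced model without the SCA
#'   main term (for likelihood-ratio testing of sigma2_SCA). The
#'   SCA-by-location interaction is kept in both models so the test
#'   isolates the cross-specific main effect.
#' @return list with \code{vc} ([VarianceComponents-class]) and \code{fit}.
#' @export
decomposeGcaSca <- function(records, includeSca = TRUE) {
  .checkRecords(records)
  .checkMaturity(records)
  hy <- records$type == "hybrid"
  if (!any(hy)) stop("no hybrid records with parent ids")
  if (any(is.na(records$femaleId[hy]) | is.na(records$maleId[hy])))
    stop("hybrid records must carry femaleId and maleId")
  rec <- records
  rec$maturityClass <- factor(rec$maturityClass)
  rec$hyb <- as.numeric(hy)
  rec$chk <- 1 - rec$hyb
  rec$femaleId <- ifelse(hy, rec$femaleId, "none")
  rec$maleId <- ifelse(hy, rec$maleId, "none")
  rec$fm <- paste(rec$femaleId, rec$maleId, sep = ":")
  ## weakly identified GCA warning
  cr <- unique(rec[hy, c("femaleId", "maleId")])
  few <- c(names(which(table(cr$femaleId) < 2)),
           names(which(table(cr$maleId) < 2)))
  if (length(few))
    warning("parent(s) in fewer than 2 crosses (GCA weakly identified): ",
            paste(few, collapse = ", "))
  extra <- c("(0 + hyb | femaleId)", "(0 + hyb | maleId)",
             if (includeSca) "(0 + hyb | fm)")
  if (length(unique(rec$locationId)) > 1)
    extra <- c(extra,
               "(0 + hyb | femaleId:locationId)",
               "(0 + hyb | maleId:locationId)",
               "(0 + hyb | fm:locationId)")
  if (any(rec$chk > 0)) {
    extra <- c(extra, "(0 + chk | genotypeId)")
    if (length(unique(rec$locationId)) > 1)
      extra <- c(extra, "(0 + chk | genotypeId:locationId)")
  }
  form <- .reFormula(rec, genoTerm = extra[1], extra = extra[-1])
  fit <- lme4::lmer(form, data = rec, REML = TRUE, control = .lmerCtrl())
  map <- c(gcaFemale = "femaleId", gcaMale = "maleId",
           sca = "fm", check = "genotypeId",
           location = "locationId", trial = "locationId:trialId",
           block = "locationId:trialId:blockId",
           gcaFemaleXLoc = "femaleId:locationId",
           gcaMaleXLoc = "maleId:locationId",
           scaXLoc = "fm:locationId",
           checkXLoc = "genotypeId:locationId", error = "Residual")
  vc <- .vcFromFit(fit, map, rec, if (includeSca) "gca_sca" else
    "gca_only")
  s2 <- vc@sigma2
  vc@sigma2 <- c(s2, genotype = unname(s2["gcaFemale"] + s2["gcaMale"] +
                                         s2["sca"]),
                 gxl = unname(s2["gcaFemaleXLoc"] + s2["gcaMaleXLoc"] +
                                s2["scaXLoc"]))
  list(vc = vc, fit = fit)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' Evaluates
#' \deqn{h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{G\times L}/n_{loc} +
#'   \sigma^2_e/(n_{loc} n_{rep}))}
#' For unreplicated entries in augmented designs the effective number of
#' replicates within location is 1.
#'
#' @param x a [VarianceComponents-class] (components \code{genotype},
#'   \code{gxl}, \code{error}) or the numeric sigma2_G.
#' @param sigma2GxL,sigma2Error remaining components when \code{x} is
#'   numeric.
#' @param nLocations,nReplicates trial context.
#' @return broad-sense heritability in [0, 1].
#' @examples
#' heritability(0.99, 1.48, 0.59, nLocations = 3)  # 0.59
#' heritability(0.53, 2.10, 0.97, nLocations = 2)  # 0.26
#' @export
heritability <- function(x, sigma2GxL = NULL, sigma2Error = NULL,
                         nLocations = NULL, nReplicates = 1) {
  if (is(x, "VarianceComponents")) {
    s2 <- x@sigma2
    g <- unname(s2["genotype"]); gl <- unname(s2["gxl"])
    e <- unname(s2["error"])
    if (is.null(nLocations)) nLocations <- x@nLocations
    nReplicates <- x@nReplicates
  } else {
    g <- x; gl <- sigma2GxL; e <- sigma2Error
  }
  stopifnot(nLocations >= 1, nReplicates >= 1)
  denom <- g + gl / nLocations + e / (nLocations * nReplicates)
  if (denom <= 0)
    stop("heritability undefined: all variance components are zero")
  g / denom
}

#' Likelihood-ratio test of a variance component
#'
#' Statistic 2(ll_full - ll_reduced), referred to the boundary-corrected
#' null: an equal mixture of a point mass at zero and chi-squared with one
#' degree of freedom, giving p = 0.5 P(chi2_1 >= LR).
#'
#' @param full,reduced fitted models: \code{merMod} objects,
#'   [VarianceComponents-class] objects, or raw REML log-likelihoods.
#'   Fixed effects must be identical for the REML comparison to be valid.
#' @return list with \code{statistic} and \code{pvalue}.
#' @export
lrtVarianceComponent <- function(full, reduced) {
  ll <- function(x) {
    if (is(x, "VarianceComponents")) return(x@logLik)
    if (is.numeric(x)) return(as.numeric(x))
    as.numeric(logLik(x))
  }
  stat <- 2 * (ll(full) - ll(reduced))
  if (stat < -1e-4)
    stop("full-model log-likelihood below reduced model (", round(stat, 4),
         "): convergence failure")
  stat <- max(stat, 0)
  list(statistic = stat,
       pvalue = 0.5 * pchisq(stat, df = 1, lower.tail = FALSE))
}

## connectivity of genotypes through shared blocks (BFS on bipartite graph)
.designComponents <- function(records) {
  blk <- paste(records$locationId, records$blockId)
  genos <- unique(records$genotypeId)
  byBlock <- split(records$genotypeId, blk)
  byGeno <- split(blk, records$genotypeId)
  comp <- setNames(rep(NA_integer_, length(genos)), genos)
  cid <- 0L
  for (g0 in genos) {
    if (!is.na(comp[g0])) next
    cid <- cid + 1L
    frontier <- g0
    comp[g0] <- cid
    while (length(frontier)) {
      blocks <- unique(unlist(byGeno[frontier], use.names = FALSE))
      nbrs <- unique(unlist(byBlock[blocks], use.names = FALSE))
      frontier <- nbrs[is.na(comp[nbrs])]
      comp[frontier] <- cid
    }
  }
  comp
}

#' Best linear unbiased estimations (adjusted genotype means)
#'
#' Same trial model with genotype as a fixed effect; returns one adjusted
#' mean per genotype (hybrids and checks). The estimability convention is
#' intercept + genotype effect evaluated at equal weighting of the
#' maturity classes. The design must be connected: every genotype must
#' share a block chain with the rest of the design (replicated checks
#' provide the chain in augmented layouts).
#'
#' @param records plot records.
#' @return data.frame with columns genotypeId, type, blue.
#' @export
computeBlues <- function(records) {
  .checkRecords(records)
  .checkMaturity(records)
  comp <- .designComponents(records)
  if (length(unique(comp)) > 1) {
    checks <- unique(records$genotypeId[records$type == "check"])
    anchor <- if (length(checks)) comp[checks[1]] else
      as.integer(names(which.max(table(comp))))
    bad <- names(comp)[comp != anchor]
    stop("disconnected design; genotypes without a block chain to the ",
         "checks: ", paste(head(bad, 10), collapse = ", "))
  }
  rec <- records
  rec$genotypeId <- factor(rec$genotypeId)
  rec$maturityClass <- factor(rec$maturityClass)
  extra <- character()
  if (length(unique(rec$locationId)) > 1)
    extra <- c(extra, "(1 | locationId)", "(1 | genotypeId:locationId)")
  if (length(unique(paste(rec$locationId, rec$trialId))) > 1)
    extra <- c(extra, "(1 | locationId:trialId)")
  if (length(unique(paste(rec$locationId, rec$blockId))) >
      length(unique(paste(rec$locationId, rec$trialId))))
    extra <- c(extra, "(1 | locationId:trialId:blockId)")
  matLevs <- levels(rec$maturityClass)
  fixedPart <- if (length(matLevs) > 1)
    "yield ~ 0 + genotypeId + maturityClass" else "yield ~ 0 + genotypeId"
  if (length(extra)) {
    form <- as.formula(paste(fixedPart, "+", paste(extra, collapse = " + ")))
    fit <- lme4::lmer(form, data = rec, REML = TRUE, control = .lmerCtrl())
    fe <- lme4::fixef(fit)
  } else {
    fit <- stats::lm(as.formula(fixedPart), data = rec)
    fe <- coef(fit)
  }
  gl <- levels(rec$genotypeId)
  gco <- fe[paste0("genotypeId", gl)]
  mco <- fe[paste0("maturityClass", matLevs[-1])]
  mco[is.na(mco)] <- 0
  matAdj <- mean(c(0, mco))
  out <- data.frame(genotypeId = gl,
                    blue = unname(gco) + matAdj,
                    stringsAsFactors = FALSE)
  ty <- records[!duplicated(records$genotypeId),
                c("genotypeId", "type")]
  out$type <- ty$type[match(out$genotypeId, ty$genotypeId)]
  out[, c("genotypeId", "type", "blue")]
}

#' Commercial heterosis relative to the best check
#'
#' Per hybrid, the percentage yield advantage over the highest-yielding
#' check variety: 100 (BLUE_hybrid - BLUE_bestcheck) / BLUE_bestcheck.
#'
#' @param blues BLUE table from [computeBlues()] (columns genotypeId,
#'   type, blue).
#' @return list with \code{perHybrid} (data.frame genotypeId, pct),
#'   \code{best} (value for the best hybrid), \code{bestCheck} (id of the
#'   reference check).
#' @export
commercialHeterosis <- function(blues) {
  chk <- blues[blues$type == "check", , drop = FALSE]
  if (!nrow(chk)) stop("no checks present; commercial heterosis undefined")
  hyb <- blues[blues$type == "hybrid", , drop = FALSE]
  b <- max(chk$blue)
  bestCheck <- chk$genotypeId[which.max(chk$blue)]
  pct <- 100 * (hyb$blue - b) / b
  list(perHybrid = data.frame(genotypeId = hyb$genotypeId, pct = pct,
                              stringsAsFactors = FALSE),
       best = if (length(pct)) max(pct) else NA_real_,
       bestCheck = bestCheck)
}
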