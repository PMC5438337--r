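## balanced two-location factorial used for oracle comparisons: every
## genotype once per trial, two trials per location
balancedTrialRecords <- function(nGeno = 20, seed = 31, s2g = 0.6,
                                 s2loc = 0.3, s2trial = 0.15, s2gl = 0.4,
                                 s2e = 0.5) {
  set.seed(seed)
  genos <- sprintf("g%02d", seq_len(nGeno))
  g <- setNames(rnorm(nGeno, 0, sqrt(s2g)), genos)
  recs <- list()
  for (loc in c("LOC1", "LOC2")) {
    l <- rnorm(1, 0, sqrt(s2loc))
    gl <- setNames(rnorm(nGeno, 0, sqrt(s2gl)), genos)
    for (tr in c("T1", "T2")) {
      t <- rnorm(1, 0, sqrt(s2trial))
      recs[[paste(loc, tr)]] <- data.frame(
        genotypeId = genos, type = "hybrid",
        femaleId = NA, maleId = NA,
        locationId = loc, trialId = tr, blockId = paste0(tr, ".B1"),
        maturityClass = "mat1",
        yield = 5 + g + l + t + gl + rnorm(nGeno, 0, sqrt(s2e)))
    }
  }
  do.call(rbind, recs)
}

test_that("noiseless data recover the genotypic variance exactly", {
  cfg <- simConfig(nMale = 10, nFemale = 4, nHybrids = 28, nMarkers = 80,
                   varLocation = 0, varTrial = 0, varBlock = 0, varGxL = 0,
                   varError = 0, maturityEffects = 0, seed = 13)
  prog <- simulateProgram(cfg)
  ef <- attr(prog$plots, "effects")
  fit <- fitTrialModel(prog$plots)
  truth <- var(ef$genotypeValue[unique(prog$plots$genotypeId)])
  expect_lt(abs(fit$vc@sigma2[["genotype"]] / truth - 1), 1e-3)
  expect_true(all(fit$vc@sigma2[c("location", "trial", "block", "gxl",
                                  "error")] < 1e-8))
})

test_that("REML components match a hand-coded EM-REML oracle", {
  rec <- balancedTrialRecords(nGeno = 20, seed = 31)
  fit <- fitTrialModel(rec)
  ## dense EM-REML on the same model (genotype, location, trial-in-
  ## location, genotype-by-location, residual)
  mkZ <- function(f) {
    f <- factor(f)
    stats::model.matrix(~ 0 + f)
  }
  Z <- list(genotype = mkZ(rec$genotypeId),
            location = mkZ(rec$locationId),
            trial = mkZ(paste(rec$locationId, rec$trialId)),
            gxl = mkZ(paste(rec$genotypeId, rec$locationId)))
  s2 <- emRemlOracle(rec$yield, matrix(1, nrow(rec), 1), Z, tol = 1e-12,
                     maxit = 30000)
  got <- fit$vc@sigma2[c("genotype", "location", "trial", "gxl", "error")]
  expect_equal(unname(got), s2, tolerance = 1e-4)
})

test_that("heritability evaluates the entry-mean formula exactly", {
  ## long-grain and medium-grain worked examples
  expect_equal(round(heritability(0.99, 1.48, 0.59, nLocations = 3), 2),
               0.59)
  expect_equal(round(heritability(0.53, 2.10, 0.97, nLocations = 2), 2),
               0.26)
  ## no GxL and no error -> 1
  expect_equal(heritability(0.8, 0, 0, nLocations = 2), 1)
  ## monotonicity
  expect_gt(heritability(1.2, 1, 1, 2), heritability(0.8, 1, 1, 2))
  expect_lt(heritability(1, 2, 1, 2), heritability(1, 1, 1, 2))
  expect_lt(heritability(1, 1, 2, 2), heritability(1, 1, 1, 2))
  ## degenerate input errors
  expect_error(heritability(0, 0, 0, nLocations = 2), "undefined")
})

test_that("variance-component LRT uses the boundary-corrected null", {
  same <- lrtVarianceComponent(-100.0, -100.0)
  expect_equal(same$statistic, 0)
  expect_equal(same$pvalue, 0.5)
  crit <- lrtVarianceComponent(-100, -100 - 2.706 / 2)
  expect_equal(crit$pvalue, 0.05, tolerance = 1e-3)
  expect_error(lrtVarianceComponent(-101, -100), "convergence")
})

test_that("BLUEs equal raw means on balanced designs and de-shift augmented blocks", {
  ## balanced complete: every genotype in every block
  set.seed(21)
  genos <- sprintf("g%02d", 1:8)
  gv <- setNames(rnorm(8), genos)
  rec <- expand.grid(genotypeId = genos, blockId = c("B1", "B2"),
                     stringsAsFactors = FALSE)
  rec$type <- "hybrid"; rec$locationId <- "LOC1"; rec$trialId <- "T1"
  rec$maturityClass <- "mat1"
  rec$yield <- 5 + gv[rec$genotypeId] + rnorm(nrow(rec), 0, 0.3)
  bl <- computeBlues(rec)
  raw <- tapply(rec$yield, rec$genotypeId, mean)
  expect_equal(bl$blue[match(names(raw), bl$genotypeId)], as.numeric(raw),
               tolerance = 1e-8)

  ## augmented design with a +1 contamination of block B2: entries grown
  ## there must be adjusted downwards relative to their raw means
  ent <- sprintf("e%02d", 1:10)
  ev <- setNames(rnorm(10, 0, 0.5), ent)
  b1 <- data.frame(genotypeId = c(ent[1:5], "c1", "c2"), blockId = "B1")
  b2 <- data.frame(genotypeId = c(ent[6:10], "c1", "c2"), blockId = "B2")
  aug <- rbind(b1, b2)
  aug$type <- ifelse(grepl("^c", aug$genotypeId), "check", "hybrid")
  aug$locationId <- "LOC1"; aug$trialId <- "T1"; aug$maturityClass <- "mat1"
  base <- c(ev, c1 = 0.2, c2 = -0.1)
  aug$yield <- 5 + base[aug$genotypeId] + ifelse(aug$blockId == "B2", 1, 0)
  bl2 <- computeBlues(aug)
  raw2 <- tapply(aug$yield, aug$genotypeId, mean)
  gapRaw <- mean(raw2[ent[6:10]]) - mean(raw2[ent[1:5]])
  blv <- setNames(bl2$blue, bl2$genotypeId)
  gapBlue <- mean(blv[ent[6:10]]) - mean(blv[ent[1:5]])
  gapTrue <- mean(ev[ent[6:10]]) - mean(ev[ent[1:5]])
  expect_lt(abs(gapBlue - gapTrue), abs(gapRaw - gapTrue))

  ## noiseless augmented data reproduce truth + mu exactly
  aug0 <- aug
  aug0$yield <- 5 + base[aug0$genotypeId]
  bl0 <- computeBlues(aug0)
  expect_equal(setNames(bl0$blue, bl0$genotypeId)[ent],
               5 + ev, tolerance = 1e-8)
})

test_that("disconnected designs are rejected with the offending genotypes", {
  rec <- data.frame(
    genotypeId = c("g1", "g2", "c1", "g3", "g4"),
    type = c("hybrid", "hybrid", "check", "hybrid", "hybrid"),
    locationId = "LOC1", trialId = "T1",
    blockId = c("B1", "B1", "B1", "B2", "B2"),
    maturityClass = "mat1",
    yield = c(5, 6, 4, 7, 8))
  expect_error(computeBlues(rec), "disconnected.*g3")
})

test_that("GCA/SCA estimates match the balanced-factorial ANOVA oracle", {
  set.seed(41)
  fem <- c("F1", "F2"); mal <- c("M1", "M2")
  fEff <- c(F1 = 0.5, F2 = -0.5)
  mEff <- c(M1 = 0.8, M2 = -0.8)
  sEff <- matrix(c(0.4, -0.4, -0.4, 0.4), 2, 2,
                 dimnames = list(fem, mal))
  r <- 60
  grid <- expand.grid(femaleId = fem, maleId = mal, rep = seq_len(r),
                      stringsAsFactors = FALSE)
  rec <- data.frame(
    genotypeId = paste(grid$femaleId, grid$maleId, sep = "x"),
    type = "hybrid", femaleId = grid$femaleId, maleId = grid$maleId,
    locationId = "LOC1", trialId = "T1", blockId = "T1.B1",
    maturityClass = "mat1",
    yield = 6 + fEff[grid$femaleId] + mEff[grid$maleId] +
      sEff[cbind(grid$femaleId, grid$maleId)] +
      rnorm(nrow(grid), 0, 0.1))
  dec <- decomposeGcaSca(rec)
  ## ANOVA (expected mean squares) estimators for the balanced factorial
  cell <- tapply(rec$yield, list(rec$femaleId, rec$maleId), mean)
  msE <- sum((rec$yield - cell[cbind(rec$femaleId, rec$maleId)])^2) /
    (nrow(rec) - 4)
  fm <- rowMeans(cell); mm <- colMeans(cell); gm <- mean(cell)
  msF <- r * 2 * sum((fm - gm)^2) / 1
  msM <- r * 2 * sum((mm - gm)^2) / 1
  msI <- r * sum((sweep(sweep(cell, 1, fm), 2, mm) + gm)^2) / 1
  oracle <- c(gcaFemale = (msF - msI) / (2 * r),
              gcaMale = (msM - msI) / (2 * r),
              sca = (msI - msE) / r,
              error = msE)
  got <- dec$vc@sigma2[names(oracle)]
  expect_equal(unname(got), unname(oracle), tolerance = 0.01)
  ## decomposition identity
  expect_equal(dec$vc@sigma2[["genotype"]],
               sum(dec$vc@sigma2[c("gcaFemale", "gcaMale", "sca")]))
})

test_that("decomposed genetic variance agrees with the joint genotype variance", {
  ## balanced 22x18 factorial at two locations; the agreement between the
  ## joint and the decomposed genetic variance is asymptotic in the
  ## factorial size (the joint model ignores the parent-sharing
  ## covariance, a 1/n effect), so a reasonably large factorial is used
  set.seed(51)
  fem <- sprintf("F%d", 1:18); mal <- sprintf("M%d", 1:22)
  fEff <- setNames(rnorm(18, 0, 0.5), fem)
  mEff <- setNames(rnorm(22, 0, 0.6), mal)
  sEff <- matrix(rnorm(18 * 22, 0, 0.4), 18, 22, dimnames = list(fem, mal))
  recs <- list()
  for (loc in c("LOC1", "LOC2")) {
    for (b in c("B1")) {
      grid <- expand.grid(femaleId = fem, maleId = mal,
                          stringsAsFactors = FALSE)
      grid$yield <- 6 + fEff[grid$femaleId] + mEff[grid$maleId] +
        sEff[cbind(grid$femaleId, grid$maleId)] + rnorm(18 * 22, 0, 0.3)
      recs[[paste(loc, b)]] <- data.frame(
        genotypeId = paste(grid$femaleId, grid$maleId, sep = "x"),
        type = "hybrid", femaleId = grid$femaleId, maleId = grid$maleId,
        locationId = loc, trialId = "T1", blockId = paste0("T1.", b),
        maturityClass = "mat1", yield = grid$yield)
    }
  }
  rec <- do.call(rbind, recs)
  joint <- fitTrialModel(rec)$vc@sigma2[["genotype"]]
  dec <- decomposeGcaSca(rec)$vc@sigma2[["genotype"]]
  expect_lt(abs(dec / joint - 1), 0.05)
})

test_that("REML results are invariant to yield rescaling", {
  rec <- balancedTrialRecords(nGeno = 15, seed = 61)
  f1 <- fitTrialModel(rec)
  rec2 <- rec; rec2$yield <- rec2$yield * 100
  f2 <- fitTrialModel(rec2)
  expect_equal(unname(f2$vc@sigma2), unname(f1$vc@sigma2) * 1e4,
               tolerance = 1e-4)
  expect_equal(heritability(f1$vc), heritability(f2$vc), tolerance = 1e-6)
  b1 <- computeBlues(rec); b2 <- computeBlues(rec2)
  expect_identical(order(b1$blue), order(b2$blue))
})

test_that("commercial heterosis contrasts hybrids with the best check", {
  bl <- data.frame(genotypeId = c("h1", "h2", "h3", "c1", "c2"),
                   type = c("hybrid", "hybrid", "hybrid", "check", "check"),
                   blue = c(12.5, 10.0, 9.0, 10.0, 8.0))
  ch <- commercialHeterosis(bl)
  expect_equal(ch$best, 25)
  expect_equal(ch$perHybrid$pct[ch$perHybrid$genotypeId == "h2"], 0)
  expect_equal(ch$bestCheck, "c1")
  ## all hybrids below the best check -> all negative
  bl2 <- bl; bl2$blue[1:3] <- c(9, 8, 7)
  expect_true(all(commercialHeterosis(bl2)$perHybrid$pct < 0))
  expect_error(commercialHeterosis(bl[1:3, ]), "no checks")
})
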