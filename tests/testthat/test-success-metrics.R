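mkPattern <- function(g1, g2, score = 0) {
  new("HeteroticPattern", group1 = sort(g1), group2 = sort(g2),
      score = score, size = length(g1), metadata = list())
}

mkEffects <- function(mu, a, d) {
  new("MarkerEffects", mu = mu,
      a = setNames(a, paste0("m", seq_along(a))),
      d = setNames(d, paste0("m", seq_along(a))),
      lambdaA = 1, lambdaD = 1)
}

test_that("selection limit enumerates the best fixable allele combination", {
  ## both groups segregate both alleles: max(+a, -a, d)
  g <- toyGenotypes(rbind(L1 = 2, L2 = 0, L3 = 2, L4 = 0))
  colnames(g@dosage) <- "m1"
  g@markerInfo$markerId <- "m1"
  pat <- mkPattern(c("L1", "L2"), c("L3", "L4"))
  expect_equal(selectionLimit(mkEffects(10, 2, 1), pat, g), 12)
  ## overdominance: heterozygote optimal
  expect_equal(selectionLimit(mkEffects(10, 0.5, 3), pat, g), 13)
  ## fixation constraints: group1 only carries the low allele
  g2 <- toyGenotypes(rbind(L1 = 0, L2 = 0, L3 = 2, L4 = 0))
  colnames(g2@dosage) <- "m1"
  g2@markerInfo$markerId <- "m1"
  ## choices: (low, high) -> d; (low, low) -> -a
  expect_equal(selectionLimit(mkEffects(10, 2, 1), pat, g2), 11)
  expect_equal(selectionLimit(mkEffects(10, 2, -5), pat, g2), 8)
})

test_that("selection limit equals the per-locus exhaustive oracle", {
  set.seed(91)
  for (rep in 1:50) {
    d <- matrix(2 * rbinom(8 * 20, 1, runif(1, 0.2, 0.8)), 8, 20)
    rownames(d) <- paste0("L", 1:8)
    colnames(d) <- paste0("m", 1:20)
    g <- toyGenotypes(d)
    a <- rnorm(20); dd <- rnorm(20)
    eff <- mkEffects(5, a, dd)
    pat <- mkPattern(paste0("L", 1:3), paste0("L", 4:6))
    got <- selectionLimit(eff, pat, g)
    want <- selectionLimitOracle(5, a, dd, d[1:3, , drop = FALSE],
                                 d[4:6, , drop = FALSE])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("selection limit dominates scores and grows with nested groups", {
  prog <- smallProgram(seed = 92)
  parents <- prog$parents
  eff <- mkEffects(5, unname(prog$truth$a), unname(prog$truth$d))
  names(eff@a) <- names(eff@d) <- markerIds(parents)
  H <- fullDiallel(eff, parents)
  ids <- lineIds(parents)
  pat <- mkPattern(ids[1:4], ids[5:8])
  lim <- selectionLimit(eff, pat, parents)
  ## the per-locus optimum dominates every realized inter-group cross
  expect_gte(lim, max(H[ids[1:4], ids[5:8]]) - 1e-8)
  ## nested growth: adding lines can only extend the fixable allele sets
  pat2 <- mkPattern(ids[1:6], ids[7:12])
  pat2small <- mkPattern(ids[1:4], ids[7:10])
  expect_gte(selectionLimit(eff, pat2, parents),
             selectionLimit(eff, pat2small, parents) - 1e-8)
  pat3 <- mkPattern(ids[1:2], ids[5:6])
  expect_gte(lim, selectionLimit(eff, pat3, parents) - 1e-8)
})

test_that("representativeness follows the coverage-minus-redundancy index", {
  ids <- paste0("L", 1:4)
  A <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  A["L1", "L2"] <- A["L2", "L1"] <- 0.9
  A["L3", "L4"] <- A["L4", "L3"] <- 0.9
  diag(A) <- 1
  r <- representativeness(A, list(group1 = c("L1"), group2 = c("L2")), ids)
  expect_equal(as.numeric(r), 2 * 0.7 - 0.9)
  ## clonal population: everything related at 1 -> R = 1
  A1 <- matrix(1, 4, 4, dimnames = list(ids, ids))
  r1 <- representativeness(A1, list(group1 = "L1", group2 = "L2"), ids)
  expect_equal(as.numeric(r1), 1)
  ## selecting the full population returns its mean off-diagonal kinship
  rAll <- representativeness(A, list(group1 = c("L1", "L2"),
                                     group2 = c("L3", "L4")), ids)
  off <- A[upper.tri(A)]
  expect_equal(as.numeric(rAll), mean(off))
  ## duplicating a selected line cannot increase the index
  ids5 <- c(ids, "L5")
  A5 <- rbind(cbind(A, A[, "L1"]), c(A["L1", ], 1))
  dimnames(A5) <- list(ids5, ids5)
  r5 <- representativeness(A5, list(group1 = c("L1", "L5"), group2 = "L2"),
                           ids)
  expect_lte(as.numeric(r5), as.numeric(r))
  expect_error(representativeness(A, list(group1 = character(),
                                          group2 = character()), ids),
               "empty")
})

test_that("pool comparison reports the percent advantage of the pattern", {
  ids <- c(paste0("F", 1:4), paste0("M", 1:6))
  H <- matrix(NA_real_, 10, 10, dimnames = list(ids, ids))
  fm <- expand.grid(f = paste0("F", 1:4), m = paste0("M", 1:6),
                    stringsAsFactors = FALSE)
  vals <- seq(1, 2, length.out = nrow(fm))
  H[cbind(fm$f, fm$m)] <- vals
  H[cbind(fm$m, fm$f)] <- vals
  ## pattern cells uniformly 1.09 x the pool cells -> 9 percent
  pat <- mkPattern(paste0("M", 1:2), paste0("M", 3:4))
  H[cbind(rep(paste0("M", 1:2), each = 2), rep(paste0("M", 3:4), 2))] <-
    1.09 * vals[1:4]
  H[cbind(rep(paste0("M", 3:4), 2), rep(paste0("M", 1:2), each = 2))] <-
    1.09 * vals[1:4]
  cmpAll <- compareToPools(H, paste0("F", 1:4), paste0("M", 1:6), pat,
                           k = 4)
  identical_idx <- sort(vals, decreasing = TRUE)[1:4]
  expect_equal(cmpAll$meanPool, mean(identical_idx))
  ## identical distributions give zero advantage
  patEq <- mkPattern("F1", "M6")
  H["F1", "M6"] <- H["M6", "F1"] <- max(vals)
  cmp0 <- compareToPools(H, "F1", "M6", patEq, k = 1)
  expect_equal(cmp0$pctAdvantage, 0)
  ## uniform 1.09 ratio
  H2 <- matrix(NA_real_, 10, 10, dimnames = list(ids, ids))
  H2[cbind(fm$f, fm$m)] <- 2; H2[cbind(fm$m, fm$f)] <- 2
  H2[cbind(rep(paste0("M", 1:2), each = 2), rep(paste0("M", 3:4), 2))] <- 2.18
  H2[cbind(rep(paste0("M", 3:4), 2), rep(paste0("M", 1:2), each = 2))] <- 2.18
  cmp9 <- compareToPools(H2, paste0("F", 1:4), paste0("M", 1:6), pat, k = 4)
  expect_equal(cmp9$pctAdvantage, 9, tolerance = 1e-10)
  ## k beyond the defined cells errors; empty pools error
  expect_error(compareToPools(H2, paste0("F", 1:4), paste0("M", 1:6), pat,
                              k = 100), "exceeds")
  expect_error(compareToPools(H2, character(), paste0("M", 1:6), pat),
               "empty pool")
  ## s^2 < k truncation is flagged
  cmpT <- compareToPools(H2, paste0("F", 1:4), paste0("M", 1:6), pat, k = 10)
  expect_true(cmpT$patternTruncated)
})

test_that("plateau detection finds the 95 percent saturation size", {
  sizes <- 2:20
  lim <- 10 * (1 - exp(-(sizes - 1) / 4))      # saturating
  rep_ <- 1 - exp(-(sizes - 1) / 4.2)
  pl <- detectPlateau(sizes, lim, rep_)
  ## both curves cross 95 percent of max around 13-14
  expect_equal(pl$size, sizes[min(which(lim >= 0.95 * max(lim) &
                                          rep_ >= 0.95 * max(rep_)))])
  expect_false(pl$insufficientSweep)
  ## flat curves plateau immediately
  expect_equal(detectPlateau(sizes, rep(1, 19), rep(1, 19))$size, 2)
  ## single-size sweep is flagged
  pl1 <- detectPlateau(5, 1, 1)
  expect_equal(pl1$size, 5)
  expect_true(pl1$insufficientSweep)
})

test_that("the success report aggregates per-size metrics and the plateau", {
  prog <- smallProgram(seed = 93)
  parents <- prog$parents
  eff <- mkEffects(5, unname(prog$truth$a), unname(prog$truth$d))
  names(eff@a) <- names(eff@d) <- markerIds(parents)
  H <- fullDiallel(eff, parents)
  A <- additiveRelationship(rogersDistance(parents))
  sw <- sizeSweep(H, sizes = 2:4, seed = 5)
  pl <- pools(parents)
  rep_ <- buildSuccessReport(eff, H, A, sw, parents,
                             femaleIds = names(pl)[pl == "female"],
                             maleIds = names(pl)[pl == "male"],
                             comparisonSize = 4, k = 16)
  expect_equal(rep_$perSize$size, 2:4)
  ## the limit dominates the score at every size
  expect_true(all(rep_$perSize$limit >= rep_$perSize$score - 1e-8))
  expect_true(all(rep_$perSize$representativeness >= 0 &
                    rep_$perSize$representativeness <= 1))
  expect_true(rep_$plateau$size %in% 2:4)
  expect_equal(rep_$comparison$size, 4)
  expect_true(is.finite(rep_$comparison$pctAdvantage))
})
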