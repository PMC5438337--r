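#' Theoretical selection limit under reciprocal recurrent selection
#'
#' The maximum hybrid performance reachable by fixing, per locus, the best
#' allele combination available in the two heterotic groups (no migration,
#' mutation or epistasis): an allele is fixable in a group when at least
#' one member carries it. With additive effect a and dominance effect d at
#' a marker the attainable F-infinity genotypic values are +a (both groups
#' fix the reference homozygote), -a (both fix the alternative) and d
#' (opposite fixation, permanently heterozygous hybrid); the limit is the
#' intercept plus the per-locus maximum over the admissible choices.
#' Markers with all-missing calls inside a group are skipped with a
#' message.
#'
#' @param effects a [MarkerEffects-class].
#' @param pattern a [HeteroticPattern-class].
#' @param parents a [GenotypeMatrix-class] covering both groups on the
#'   same marker panel as \code{effects}.
#' @return the selection limit (same units as the training performance).
#' @export
selectionLimit <- function(effects, pattern, parents) {
  mk <- names(effects@a)
  if (!setequal(mk, markerIds(parents)))
    stop("effects and parent genotypes must share the marker panel")
  d <- dosage(parents)[, mk, drop = FALSE]
  g1 <- pattern@group1; g2 <- pattern@group2
  miss <- setdiff(c(g1, g2), lineIds(parents))
  if (length(miss)) stop("pattern members not genotyped: ",
                         paste(miss, collapse = ", "))
  present <- function(rows) {
    sub <- d[rows, , drop = FALSE]
    ## columns: can the group fix the alternative (0) / reference (2)?
    hasLow <- apply(sub, 2, function(v) any(v[!is.na(v)] %in% c(0, 1)))
    hasHigh <- apply(sub, 2, function(v) any(v[!is.na(v)] %in% c(1, 2)))
    allMiss <- apply(sub, 2, function(v) all(is.na(v)))
    list(low = hasLow, high = hasHigh, allMiss = allMiss)
  }
  p1 <- present(g1); p2 <- present(g2)
  skip <- p1$allMiss | p2$allMiss
  if (any(skip))
    message(sum(skip), " marker(s) skipped: all calls missing within a group")
  a <- effects@a[mk]; dd <- effects@d[mk]
  total <- 0
  for (j in which(!skip)) {
    cand <- c(
      if (p1$high[j] && p2$high[j]) a[j],
      if (p1$low[j] && p2$low[j]) -a[j],
      if ((p1$high[j] && p2$low[j]) || (p1$low[j] && p2$high[j])) dd[j])
    total <- total + max(cand)
  }
  unname(effects@mu + total)
}

#' Genetic representativeness of a heterotic pattern
#'
#' Index of how much of the full population's genome the selected groups
#' cover, computed from additive relationships (A = 1 - Rogers' distance):
#' \deqn{R = 2\,\bar a(P, G) - \bar a(G, G)}
#' where G is the union of both groups, abar(P,G) averages, over
#' population lines, each line's mean relationship to the group members
#' (a line's relationship to itself excluded), and abar(G,G) is the mean
#' relationship over unordered within-group pairs (diagonal excluded).
#' The first term rewards coverage of the population, the second
#' penalizes redundancy within the selected set. The value is clamped to
#' [0, 1] with a \code{clamped} attribute when clamping occurred.
#'
#' @param A additive relationship matrix covering all ids.
#' @param pattern a [HeteroticPattern-class] (or list with group1/group2).
#' @param populationIds ids of the full population P.
#' @return representativeness in [0, 1].
#' @export
representativeness <- function(A, pattern, populationIds) {
  g <- if (is(pattern, "HeteroticPattern"))
    union(pattern@group1, pattern@group2) else
      union(pattern$group1, pattern$group2)
  if (!length(g)) stop("empty group")
  miss <- setdiff(c(g, populationIds), rownames(A))
  if (length(miss)) stop("ids absent from relationship matrix: ",
                         paste(miss, collapse = ", "))
  if (length(g) < 2) stop("need at least 2 selected lines")
  rp <- vapply(populationIds, function(p) {
    others <- setdiff(g, p)
    mean(A[p, others])
  }, numeric(1))
  aPG <- mean(rp)
  pairs <- combn(g, 2)
  aGG <- mean(A[cbind(pairs[1, ], pairs[2, ])])
  r <- 2 * aPG - aGG
  clamped <- r < 0 || r > 1
  r <- min(max(r, 0), 1)
  attr(r, "clamped") <- clamped
  r
}

#' Compare a heterotic pattern to the existing pool crosses
#'
#' Contrasts the top-k predicted female x male crosses of the current
#' pools (distribution A) with the top-k inter-group crosses of the
#' pattern (distribution B; all s^2 crosses with a flag when s^2 < k) and
#' reports the percent advantage 100 (mean_B - mean_A) / mean_A.
#'
#' @param H symmetric predicted-performance matrix over all lines.
#' @param femaleIds,maleIds ids of the current female and male pools.
#' @param pattern a [HeteroticPattern-class].
#' @param k standardized population size (number of crosses compared).
#' @return list with meanPool, meanPattern, pctAdvantage, k, and flags.
#' @export
compareToPools <- function(H, femaleIds, maleIds, pattern, k = 256) {
  .checkScoreMatrix(H)
  if (!length(femaleIds) || !length(maleIds))
    stop("empty pool set")
  sub <- H[femaleIds, maleIds, drop = FALSE]
  cells <- sub[!is.na(sub)]
  if (k > length(cells))
    stop("k = ", k, " exceeds the ", length(cells),
         " defined female x male cells")
  topPool <- sort(cells, decreasing = TRUE)[seq_len(k)]
  inter <- H[pattern@group1, pattern@group2, drop = FALSE]
  interCells <- sort(as.vector(inter), decreasing = TRUE)
  truncated <- length(interCells) < k
  topPattern <- interCells[seq_len(min(k, length(interCells)))]
  mA <- mean(topPool); mB <- mean(topPattern)
  list(meanPool = mA, meanPattern = mB,
       pctAdvantage = 100 * (mB - mA) / mA,
       k = k, nPatternCells = length(topPattern),
       patternTruncated = truncated)
}

#' Detect the plateau size of the long-term success curves
#'
#' Smallest group size at which both long-term curves (selection limit
#' and representativeness) reach 95 percent of their respective maxima
#' over the sweep. Flat curves plateau at the smallest size; a
#' single-size sweep is flagged as insufficient. Note the rule is applied
#' to the raw curves, so for curves with a large offset relative to their
#' dynamic range it saturates early; it mirrors reading the knee off a
#' plotted curve.
#'
#' @param sizes integer vector of group sizes.
#' @param limit,repres the two long-term curves, one value per size.
#' @param frac plateau threshold as a fraction of the maximum.
#' @return list with \code{size} and \code{insufficientSweep}.
#' @export
detectPlateau <- function(sizes, limit, repres, frac = 0.95) {
  stopifnot(length(sizes) == length(limit), length(limit) == length(repres))
  o <- order(sizes)
  sizes <- sizes[o]; limit <- limit[o]; repres <- repres[o]
  ok <- limit >= frac * max(limit) & repres >= frac * max(repres)
  list(size = sizes[which(ok)[1]],
       insufficientSweep = length(sizes) < 2)
}

#' Assemble the per-size success report
#'
#' For every size of a [sizeSweep()] result, tabulates the short-term
#' score (mean predicted inter-group performance), the theoretical
#' selection limit and the genetic representativeness, detects the
#' plateau of the long-term curves, and (when pool ids are supplied)
#' compares the pattern at \code{comparisonSize} with the top-k existing
#' pool crosses.
#'
#' @param effects a [MarkerEffects-class].
#' @param H symmetric predicted-performance matrix.
#' @param A additive relationship matrix.
#' @param sweep result of [sizeSweep()].
#' @param parents a [GenotypeMatrix-class].
#' @param populationIds full-population ids (defaults to all parents).
#' @param femaleIds,maleIds optional current pools for the comparison.
#' @param comparisonSize pattern size used in the pool comparison.
#' @param k standardized number of crosses in the comparison.
#' @return list of class \code{SuccessReport}: \code{perSize} data.frame
#'   (size, score, limit, representativeness), \code{plateau}, and
#'   optionally \code{comparison}.
#' @export
buildSuccessReport <- function(effects, H, A, sweep, parents,
                               populationIds = lineIds(parents),
                               femaleIds = NULL, maleIds = NULL,
                               comparisonSize = NULL, k = 256) {
  pats <- sweep$patterns
  sizes <- as.integer(names(pats))
  rows <- lapply(seq_along(sizes), function(i) {
    p <- pats[[i]]
    data.frame(size = sizes[i],
               score = p@score,
               limit = selectionLimit(effects, p, parents),
               representativeness =
                 as.numeric(representativeness(A, p, populationIds)))
  })
  perSize <- do.call(rbind, rows)
  plateau <- detectPlateau(perSize$size, perSize$limit,
                           perSize$representativeness)
  out <- list(perSize = perSize, plateau = plateau)
  if (!is.null(femaleIds) && !is.null(maleIds)) {
    if (is.null(comparisonSize))
      comparisonSize <- sizes[length(sizes)]
    p <- pats[[as.character(comparisonSize)]]
    kUse <- min(k, sum(!is.na(H[femaleIds, maleIds])))
    out$comparison <- compareToPools(H, femaleIds, maleIds, p, k = kUse)
    out$comparison$size <- comparisonSize
  }
  class(out) <- "SuccessReport"
  out
}
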