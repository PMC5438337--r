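.checkScoreMatrix <- function(H) {
  stopifnot(is.matrix(H), nrow(H) == ncol(H),
            !is.null(rownames(H)), identical(rownames(H), colnames(H)))
}

#' Score of a heterotic pattern
#'
#' The arithmetic mean of the predicted performance matrix over all s^2
#' inter-group crosses (the matrix is read symmetrically; the diagonal is
#' never touched because the groups are disjoint).
#'
#' @param H symmetric predicted-performance matrix ([fullDiallel()] in
#'   \code{"all"} mode).
#' @param g1,g2 disjoint character vectors of line ids of equal relevance
#'   (sizes may differ for scoring, though searches use equal sizes).
#' @return mean inter-group predicted performance.
#' @export
patternScore <- function(H, g1, g2) {
  .checkScoreMatrix(H)
  if (length(intersect(g1, g2)))
    stop("groups overlap: ", paste(intersect(g1, g2), collapse = ", "))
  miss <- setdiff(c(g1, g2), rownames(H))
  if (length(miss)) stop("lines absent from matrix: ",
                         paste(miss, collapse = ", "))
  vals <- H[g1, g2, drop = FALSE]
  if (any(is.na(vals))) stop("missing cell(s) in the inter-group block")
  mean(vals)
}

.newPattern <- function(g1, g2, score, metadata) {
  ## canonical order: group containing the lexicographically smallest id
  ## first, members sorted
  g1 <- sort(g1); g2 <- sort(g2)
  if (g2[1] < g1[1]) { tmp <- g1; g1 <- g2; g2 <- tmp }
  new("HeteroticPattern", group1 = g1, group2 = g2, score = score,
      size = length(g1), metadata = metadata)
}

#' Simulated-annealing search for the best heterotic pattern
#'
#' Searches for two disjoint groups of size s maximizing the mean
#' predicted inter-group performance. The move set swaps one member of a
#' randomly chosen group with a random non-member; moves are accepted with
#' probability min(1, exp(delta/T)) under geometric cooling T <- alpha T.
#' The initial temperature is calibrated from a sample of moves so that
#' roughly 80 percent of score-decreasing moves are initially accepted.
#' The best pattern ever visited across all restarts is returned; the
#' result is deterministic given the seed.
#'
#' @param H symmetric predicted-performance matrix with all inter-line
#'   cells defined.
#' @param s group size; the candidate pool must hold at least 2s lines.
#' @param seed RNG seed.
#' @param alpha geometric cooling factor.
#' @param innerSteps number of annealing steps per restart (default
#'   200 * n * s).
#' @param restarts independent restarts.
#' @param pool optional subset of line ids to search within (e.g. a
#'   single sex for CMS-practical searches); defaults to all lines.
#' @return a [HeteroticPattern-class].
#' @export
annealSearch <- function(H, s, seed = 1, alpha = 0.995, innerSteps = NULL,
                         restarts = 5, pool = NULL) {
  .checkScoreMatrix(H)
  ids <- if (is.null(pool)) rownames(H) else intersect(rownames(H), pool)
  n <- length(ids)
  if (n < 2 * s) stop("candidate pool (", n, ") smaller than 2s = ", 2 * s)
  if (is.null(innerSteps)) innerSteps <- 200L * n * s
  Hs <- H[ids, ids, drop = FALSE]
  bestScore <- -Inf; bestG1 <- NULL; bestG2 <- NULL
  iterations <- 0L; accepted <- 0L
  ## steepest-ascent polish over the single-swap neighbourhood; run after
  ## every annealing restart so the returned pattern is at least a local
  ## optimum of the move set
  polish <- function(g1, g2) {
    repeat {
      score <- mean(Hs[g1, g2])
      bestDelta <- 0; bestMove <- NULL
      out <- setdiff(seq_len(n), c(g1, g2))
      for (grp in 1:2) {
        within <- if (grp == 1) g1 else g2
        other <- if (grp == 1) g2 else g1
        for (wi in seq_len(s)) {
          oldSum <- sum(Hs[within[wi], other])
          for (cand in out) {
            delta <- (sum(Hs[cand, other]) - oldSum) / s^2
            if (delta > bestDelta + 1e-12) {
              bestDelta <- delta
              bestMove <- list(grp = grp, wi = wi, cand = cand,
                               exchange = FALSE)
            }
          }
          for (oi in seq_len(s)) {
            nw <- within; nw[wi] <- other[oi]
            no <- other; no[oi] <- within[wi]
            delta <- mean(Hs[nw, no]) - score
            if (delta > bestDelta + 1e-12) {
              bestDelta <- delta
              bestMove <- list(grp = grp, wi = wi, oi = oi,
                               exchange = TRUE)
            }
          }
        }
      }
      if (is.null(bestMove)) return(list(g1 = g1, g2 = g2, score = score))
      if (bestMove$exchange) {
        within <- if (bestMove$grp == 1) g1 else g2
        other <- if (bestMove$grp == 1) g2 else g1
        tmp <- within[bestMove$wi]
        within[bestMove$wi] <- other[bestMove$oi]
        other[bestMove$oi] <- tmp
        if (bestMove$grp == 1) { g1 <- within; g2 <- other } else {
          g2 <- within; g1 <- other }
      } else {
        if (bestMove$grp == 1) g1[bestMove$wi] <- bestMove$cand
        else g2[bestMove$wi] <- bestMove$cand
      }
    }
  }
  withSeed(seed, {
    for (rs in seq_len(restarts)) {
      perm <- sample(n)
      g1 <- perm[seq_len(s)]
      g2 <- perm[seq.int(s + 1L, 2L * s)]
      out <- setdiff(seq_len(n), c(g1, g2))
      score <- mean(Hs[g1, g2])
      ## T0 calibration: median decrease among sampled moves
      deltas <- replicate(100, {
        grp <- sample(1:2, 1)
        within <- if (grp == 1) g1 else g2
        other <- if (grp == 1) g2 else g1
        old <- within[sample.int(s, 1)]
        cand <- if (length(out)) c(out, other)[sample.int(n - s, 1)] else
          other[sample.int(s, 1)]
        if (cand %in% other) {
          ## swap across groups: approximate with member replacement delta
          (sum(Hs[cand, other[other != cand]]) -
             sum(Hs[old, other[other != cand]])) / s^2
        } else {
          (sum(Hs[cand, other]) - sum(Hs[old, other])) / s^2
        }
      })
      neg <- deltas[deltas < 0]
      ## mean(neg) and log(0.8) are both negative: T0 > 0, sized so an
      ## average score-decreasing move is accepted with probability 0.8
      T0 <- if (length(neg)) mean(neg) / log(0.8) else 1e-6
      if (!is.finite(T0) || T0 <= 0) T0 <- 1e-6
      Temp <- T0
      if (score > bestScore) {
        bestScore <- score; bestG1 <- g1; bestG2 <- g2
      }
      for (it in seq_len(innerSteps)) {
        iterations <- iterations + 1L
        grp <- sample(1:2, 1)
        if (grp == 1) { within <- g1; other <- g2 } else {
          within <- g2; other <- g1 }
        wi <- sample.int(s, 1)
        old <- within[wi]
        nonMembers <- c(out, other)
        cand <- nonMembers[sample.int(length(nonMembers), 1)]
        if (cand %in% other) {
          ## swapping with a member of the opposite group: exchange them
          oi <- which(other == cand)
          newWithin <- within; newWithin[wi] <- cand
          newOther <- other; newOther[oi] <- old
          newScore <- mean(Hs[newWithin, newOther])
          delta <- newScore - score
          if (delta > 0 || runif(1) < exp(delta / Temp)) {
            accepted <- accepted + 1L
            if (grp == 1) { g1 <- newWithin; g2 <- newOther } else {
              g2 <- newWithin; g1 <- newOther }
            score <- newScore
          }
        } else {
          delta <- (sum(Hs[cand, other]) - sum(Hs[old, other])) / s^2
          if (delta > 0 || runif(1) < exp(delta / Temp)) {
            accepted <- accepted + 1L
            within[wi] <- cand
            out <- c(setdiff(out, cand), old)
            if (grp == 1) g1 <- within else g2 <- within
            score <- score + delta
          }
        }
        if (it %% 1000L == 0L) score <- mean(Hs[g1, g2])  # kill fp drift
        if (score > bestScore + 1e-12) {
          bestScore <- score; bestG1 <- g1; bestG2 <- g2
        }
        Temp <- Temp * alpha
      }
      pol <- polish(g1, g2)
      if (pol$score > bestScore + 1e-12) {
        bestScore <- pol$score; bestG1 <- pol$g1; bestG2 <- pol$g2
      }
      pol2 <- polish(bestG1, bestG2)
      if (pol2$score > bestScore + 1e-12) {
        bestScore <- pol2$score; bestG1 <- pol2$g1; bestG2 <- pol2$g2
      }
    }
  })
  g1 <- ids[bestG1]; g2 <- ids[bestG2]
  score <- patternScore(H, g1, g2)  # self-check recomputation
  stopifnot(abs(score - bestScore) < 1e-6)
  .newPattern(g1, g2, score,
              metadata = list(method = "anneal", seed = seed,
                              alpha = alpha, innerSteps = innerSteps,
                              restarts = restarts,
                              iterations = iterations,
                              accepted = accepted))
}

#' Exhaustive search for the best heterotic pattern
#'
#' Enumerates every unordered pair of disjoint size-s groups and returns
#' the maximum-score pattern; ties are broken lexicographically on the
#' sorted id tuples. Intended as the exact oracle for small instances.
#'
#' @param H symmetric predicted-performance matrix.
#' @param s group size.
#' @param cap maximum number of evaluated patterns.
#' @param pool optional candidate subset of line ids.
#' @return a [HeteroticPattern-class].
#' @export
bruteForceSearch <- function(H, s, cap = 2e6, pool = NULL) {
  .checkScoreMatrix(H)
  ids <- if (is.null(pool)) rownames(H) else intersect(rownames(H), pool)
  n <- length(ids)
  if (n < 2 * s) stop("candidate pool smaller than 2s")
  nEval <- choose(n, s) * choose(n - s, s) / 2
  if (nEval > cap)
    stop("search space (", format(nEval, big.mark = ","),
         " patterns) exceeds the cap; use annealSearch()")
  g1set <- combn(n, s, simplify = FALSE)
  bestScore <- -Inf; bestKey <- NULL; bestG1 <- NULL; bestG2 <- NULL
  for (g1 in g1set) {
    rest <- setdiff(seq_len(n), g1)
    for (g2 in combn(rest, s, simplify = FALSE)) {
      if (g2[1] < g1[1]) next  # count each unordered pair once
      sc <- mean(H[ids[g1], ids[g2]])
      key <- paste(c(ids[sort(c(g1[1], g2[1]))],
                     ids[g1], ids[g2]), collapse = "|")
      if (sc > bestScore + 1e-12 ||
          (abs(sc - bestScore) <= 1e-12 && !is.null(bestKey) &&
           key < bestKey)) {
        bestScore <- sc; bestKey <- key
        bestG1 <- ids[g1]; bestG2 <- ids[g2]
      }
    }
  }
  .newPattern(bestG1, bestG2, bestScore,
              metadata = list(method = "bruteforce", evaluated = nEval))
}

#' Sweep heterotic-pattern searches over group sizes
#'
#' Runs [annealSearch()] for each requested size and reports the
#' stability of the selected line sets between consecutive sizes (Jaccard
#' overlap of the unions of both groups) plus the fraction of female
#' lines selected per size (when pool labels are provided).
#'
#' @param H symmetric predicted-performance matrix.
#' @param sizes integer vector of group sizes (classically 2 to 20).
#' @param seed RNG seed (each size derives its own stream).
#' @param poolLabels optional named vector of "male"/"female" labels used
#'   for the female-selection report.
#' @param ... passed to [annealSearch()].
#' @return list with \code{patterns} (one [HeteroticPattern-class] per
#'   size) and \code{stability} (data.frame size, score, jaccardPrev,
#'   femaleFrac).
#' @export
sizeSweep <- function(H, sizes = 2:20, seed = 1, poolLabels = NULL, ...) {
  sizes <- sort(unique(as.integer(sizes)))
  patterns <- list()
  rows <- vector("list", length(sizes))
  prevSel <- NULL
  for (k in seq_along(sizes)) {
    s <- sizes[k]
    p <- annealSearch(H, s, seed = seed + s, ...)
    patterns[[as.character(s)]] <- p
    sel <- union(p@group1, p@group2)
    jac <- if (is.null(prevSel)) NA_real_ else
      length(intersect(sel, prevSel)) / length(union(sel, prevSel))
    femaleFrac <- NA_real_
    if (!is.null(poolLabels)) {
      fem <- names(poolLabels)[poolLabels == "female"]
      if (length(fem))
        femaleFrac <- length(intersect(sel, fem)) / length(fem)
    }
    rows[[k]] <- data.frame(size = s, score = p@score, jaccardPrev = jac,
                            femaleFrac = femaleFrac)
    prevSel <- sel
  }
  list(patterns = patterns, stability = do.call(rbind, rows))
}
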