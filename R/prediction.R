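## REML profile log-likelihood for the two-kernel equivalent model
## y = 1 mu + uA + uD + e with var(y) = sigma2_e (I + gA KA + gD KD).
.kernelREML <- function(logg, KA, KD, y) {
  n <- length(y)
  V0 <- diag(n) + exp(logg[1]) * KA + exp(logg[2]) * KD
  ch <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  ldV <- 2 * sum(log(diag(ch)))
  Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  xvx <- sum(Vi1)
  beta <- sum(Viy) / xvx
  r <- y - beta
  Vir <- Viy - beta * Vi1
  q <- sum(r * Vir)
  if (q <= 0) return(-1e10)
  s2 <- q / (n - 1)
  -0.5 * ((n - 1) * (1 + log(2 * pi * s2)) + ldV + log(xvx))
}

## shrinkage ratios (lambda = sigma2_e / sigma2_effect) by REML on the
## kernel form: coarse log-grid, then Nelder-Mead polish.
.estimateShrinkage <- function(Za, Zd, y) {
  KA <- tcrossprod(Za) / max(1, ncol(Za))
  KD <- tcrossprod(Zd) / max(1, ncol(Zd))
  grid <- seq(-8, 8, length.out = 7)
  best <- c(0, 0); bestLL <- -Inf
  for (ga in grid) for (gd in grid) {
    ll <- .kernelREML(c(ga, gd), KA, KD, y)
    if (ll > bestLL) { bestLL <- ll; best <- c(ga, gd) }
  }
  opt <- optim(best, function(p) -.kernelREML(p, KA, KD, y),
               method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-10))
  ## bound the variance ratios: keeps the MME well conditioned even for
  ## (near-)noiseless training data or marker columns constant in-sample
  g <- pmin(pmax(exp(opt$par), 1e-8), 1e8)
  ## kernels were scaled by marker count; per-marker gamma = g / m
  list(lambdaA = max(1, ncol(Za)) / g[1], lambdaD = max(1, ncol(Zd)) / g[2])
}

#' Fit the additive + dominance RR-BLUP model
#'
#' Solves Henderson's mixed-model equations for
#' \deqn{Y = 1_n \mu + Z_A a + Z_D d + e}
#' with ridge penalties lambda_a = sigma2_e/sigma2_a on the additive and
#' lambda_d = sigma2_e/sigma2_d on the dominance effects:
#' \deqn{\begin{bmatrix} 1'1 & 1'Z_A & 1'Z_D \\ Z_A'1 & Z_A'Z_A +
#'   \lambda_a I & Z_A'Z_D \\ Z_D'1 & Z_D'Z_A & Z_D'Z_D + \lambda_d I
#'   \end{bmatrix} \begin{bmatrix}\mu\\a\\d\end{bmatrix} =
#'   \begin{bmatrix}1'y\\Z_A'y\\Z_D'y\end{bmatrix}}
#' Covariates are centred by their training means before solving; the
#' returned intercept is re-expressed on the raw covariate scale so that
#' predictions are mu + z_A a + z_D d for uncentred codes. When the
#' shrinkage ratios are not supplied they are estimated by REML on the
#' equivalent two-kernel model of the training data.
#'
#' @param codes a [HybridCodes-class] for the training hybrids.
#' @param y observed performance (BLUEs): named numeric vector (matched by
#'   hybrid id) or a vector in the row order of \code{codes}.
#' @param lambdaA,lambdaD shrinkage ratios (> 0), or NULL to estimate.
#' @param method \code{"direct"} solves the (2m+1) MME densely,
#'   \code{"dual"} uses the equivalent n x n kernel system (identical
#'   solution; preferable when markers far outnumber hybrids);
#'   \code{"auto"} picks by size.
#' @return a [MarkerEffects-class].
#' @export
fitRRBLUP <- function(codes, y, lambdaA = NULL, lambdaD = NULL,
                      method = c("auto", "direct", "dual")) {
  method <- match.arg(method)
  stopifnot(is(codes, "HybridCodes"))
  zA <- zAdditive(codes); zD <- zDominance(codes)
  if (ncol(zA) == 0) stop("zero markers: cannot fit RR-BLUP")
  ids <- hybridInfo(codes)$hybridId
  if (!is.null(names(y))) {
    miss <- setdiff(ids, names(y))
    if (length(miss))
      stop("no observed value for hybrid(s): ",
           paste(head(miss, 5), collapse = ", "))
    y <- y[ids]
  }
  if (length(y) != nrow(zA)) stop("length(y) must match the hybrid count")
  if (any(!is.finite(y))) stop("non-finite observed values")
  y <- as.numeric(y)
  cA <- colMeans(zA); cD <- colMeans(zD)
  Za <- sweep(zA, 2, cA); Zd <- sweep(zD, 2, cD)
  if (is.null(lambdaA) || is.null(lambdaD)) {
    est <- .estimateShrinkage(Za, Zd, y)
    if (is.null(lambdaA)) lambdaA <- est$lambdaA
    if (is.null(lambdaD)) lambdaD <- est$lambdaD
  }
  stopifnot(lambdaA > 0, lambdaD > 0)
  m <- ncol(Za); n <- nrow(Za)
  if (method == "auto") method <- if (2 * m + 1 <= 1500) "direct" else "dual"
  if (method == "direct") {
    one <- rep(1, n)
    C <- rbind(
      cbind(n, t(one) %*% Za, t(one) %*% Zd),
      cbind(crossprod(Za, one), crossprod(Za) + lambdaA * diag(m),
            crossprod(Za, Zd)),
      cbind(crossprod(Zd, one), crossprod(Zd, Za),
            crossprod(Zd) + lambdaD * diag(m)))
    rhs <- c(sum(y), crossprod(Za, y), crossprod(Zd, y))
    sol <- tryCatch(solve(C, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      ## tiny shrinkage can leave the dense MME near machine-singular;
      ## the kernel form of the same equations is bounded below by I
      method <- "dual"
    } else {
      mu <- sol[1]
      a <- sol[2:(m + 1)]
      d <- sol[(m + 2):(2 * m + 1)]
    }
  }
  if (method == "dual") {
    V0 <- diag(n) + tcrossprod(Za) / lambdaA + tcrossprod(Zd) / lambdaD
    ch <- chol(V0)
    Vi <- chol2inv(ch)
    Vi1 <- rowSums(Vi)
    mu <- sum(Vi %*% y) / sum(Vi1)
    r <- as.vector(Vi %*% (y - mu))
    a <- as.vector(crossprod(Za, r)) / lambdaA
    d <- as.vector(crossprod(Zd, r)) / lambdaD
  }
  muRaw <- mu - sum(cA * a) - sum(cD * d)
  new("MarkerEffects",
      mu = unname(muRaw),
      a = setNames(as.numeric(a), colnames(zA)),
      d = setNames(as.numeric(d), colnames(zD)),
      lambdaA = lambdaA, lambdaD = lambdaD)
}

#' Predict hybrid performance from marker effects
#'
#' Deterministic evaluation of yhat = mu + z_A a + z_D d per hybrid.
#'
#' @param effects a [MarkerEffects-class].
#' @param codes a [HybridCodes-class] on the same marker panel (matched by
#'   marker id; order may differ).
#' @return named numeric vector of predictions.
#' @export
predictHybrids <- function(effects, codes) {
  zA <- zAdditive(codes); zD <- zDominance(codes)
  mk <- names(effects@a)
  if (!setequal(mk, colnames(zA)))
    stop("marker mismatch between effects and hybrid codes")
  zA <- zA[, mk, drop = FALSE]
  zD <- zD[, mk, drop = FALSE]
  p <- effects@mu + as.vector(zA %*% effects@a) +
    as.vector(zD %*% effects@d)
  setNames(p, hybridInfo(codes)$hybridId)
}

#' Predicted performance of every possible single cross
#'
#' Codes and predicts every unordered parent pair (self-crosses excluded).
#' By default lines are crossed irrespective of pool membership, returning
#' a symmetric line x line matrix with NA diagonal; \code{mode =
#' "factorial"} restricts to female x male combinations and returns a
#' female x male matrix.
#'
#' @param effects a [MarkerEffects-class].
#' @param parents a [GenotypeMatrix-class].
#' @param mode \code{"all"} or \code{"factorial"}.
#' @return predicted-performance matrix (symmetric with NA diagonal for
#'   \code{"all"}).
#' @export
fullDiallel <- function(effects, parents, mode = c("all", "factorial")) {
  mode <- match.arg(mode)
  ids <- lineIds(parents)
  if (mode == "factorial") {
    pl <- pools(parents)
    fem <- ids[pl[ids] == "female"]
    mal <- ids[pl[ids] == "male"]
    crosses <- expand.grid(femaleId = fem, maleId = mal,
                           stringsAsFactors = FALSE)
    crosses$hybridId <- paste(crosses$femaleId, crosses$maleId, sep = "x")
    pred <- predictHybrids(effects, codeHybrids(parents, crosses))
    matrix(pred, nrow = length(fem), ncol = length(mal),
           dimnames = list(fem, mal))
  } else {
    pairs <- t(combn(ids, 2))
    crosses <- data.frame(femaleId = pairs[, 1], maleId = pairs[, 2],
                          hybridId = paste(pairs[, 1], pairs[, 2],
                                           sep = "x"),
                          stringsAsFactors = FALSE)
    pred <- predictHybrids(effects, codeHybrids(parents, crosses))
    H <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
    H[cbind(pairs[, 1], pairs[, 2])] <- pred
    H[cbind(pairs[, 2], pairs[, 1])] <- pred
    H
  }
}

#' Chess-board cross-validation over relatedness scenarios
#'
#' Per run, a fraction of the female and of the male parents is sampled;
#' phenotyped crosses among the sampled parents are split into an
#' estimation set and the most-related test set T2 (a held-out fraction of
#' that block). Phenotyped crosses with exactly one sampled parent form
#' T1 and crosses among un-sampled parents form T0. Marker effects are
#' estimated on the estimation set only and the prediction ability is the
#' Pearson correlation between observed and predicted performance per
#' scenario. Runs with an empty scenario are resampled (up to
#' \code{maxAttempts} per run).
#'
#' @param codes [HybridCodes-class] of all phenotyped, genotyped hybrids.
#' @param y observed performance (named by hybrid id).
#' @param nRuns number of cross-validation runs.
#' @param fracFemale,fracMale sampled fraction of each parent sex.
#' @param estHoldout fraction of the sampled-block crosses held out as T2.
#' @param lambdaA,lambdaD optional fixed shrinkage ratios (estimated per
#'   training set when NULL).
#' @param seed RNG seed.
#' @param maxAttempts resampling cap per run.
#' @return list with \code{results} (data.frame run, scenario, ability)
#'   and \code{summary} (mean and sd of ability per scenario).
#' @export
chessboardCV <- function(codes, y, nRuns = 100, fracFemale = 0.8,
                         fracMale = 0.8, estHoldout = 0.2,
                         lambdaA = NULL, lambdaD = NULL,
                         seed = 1, maxAttempts = 100,
                         keepPartitions = FALSE) {
  hi <- hybridInfo(codes)
  if (!is.null(names(y))) y <- y[hi$hybridId]
  stopifnot(length(y) == nrow(hi), all(is.finite(y)))
  females <- unique(hi$femaleId); males <- unique(hi$maleId)
  res <- vector("list", nRuns)
  parts <- if (keepPartitions) vector("list", nRuns) else NULL
  withSeed(seed, {
    for (r in seq_len(nRuns)) {
      ok <- FALSE
      for (att in seq_len(maxAttempts)) {
        sf <- sample(females, max(1, round(fracFemale * length(females))))
        sm <- sample(males, max(1, round(fracMale * length(males))))
        both <- which(hi$femaleId %in% sf & hi$maleId %in% sm)
        nT2 <- max(1, round(estHoldout * length(both)))
        if (length(both) - nT2 < 2) next
        held <- sample(both, nT2)
        est <- setdiff(both, held)
        ## scenarios are defined by the parents actually represented in
        ## the estimation set (a sampled parent may lose all its crosses
        ## to the hold-out)
        estF <- unique(hi$femaleId[est]); estM <- unique(hi$maleId[est])
        rest <- setdiff(seq_len(nrow(hi)), est)
        inF <- hi$femaleId[rest] %in% estF
        inM <- hi$maleId[rest] %in% estM
        t2 <- rest[inF & inM]
        t1 <- rest[xor(inF, inM)]
        t0 <- rest[!inF & !inM]
        if (length(t2) < 3 || length(t1) < 3 || length(t0) < 3) next
        fitted <- tryCatch(
          fitRRBLUP(codes[est], y[est], lambdaA = lambdaA,
                    lambdaD = lambdaD),
          error = function(e) NULL)
        if (is.null(fitted)) next
        ab <- vapply(list(T2 = t2, T1 = t1, T0 = t0), function(idx) {
          p <- predictHybrids(fitted, codes[idx])
          if (length(idx) < 3 || sd(y[idx]) == 0 || sd(p) == 0)
            return(NA_real_)
          cor(y[idx], p)
        }, numeric(1))
        if (any(is.na(ab))) next
        res[[r]] <- data.frame(run = r, scenario = names(ab),
                               ability = unname(ab),
                               stringsAsFactors = FALSE)
        if (keepPartitions)
          parts[[r]] <- list(estimation = hi$hybridId[est],
                             T2 = hi$hybridId[t2], T1 = hi$hybridId[t1],
                             T0 = hi$hybridId[t0])
        ok <- TRUE
        break
      }
      if (!ok)
        stop("run ", r, ": could not build non-empty T2/T1/T0 scenarios ",
             "after ", maxAttempts, " attempts")
    }
  })
  results <- do.call(rbind, res)
  agg <- aggregate(ability ~ scenario, results,
                   function(v) c(mean = mean(v), sd = sd(v)))
  summary <- data.frame(scenario = agg$scenario,
                        mean = agg$ability[, "mean"],
                        sd = agg$ability[, "sd"])
  out <- list(results = results, summary = summary)
  if (keepPartitions) out$partitions <- parts
  out
}

#' Subset HybridCodes by row
#' @param x a HybridCodes object
#' @param i hybrid indices or ids
#' @param j,...,drop ignored
#' @export
setMethod("[", "HybridCodes", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@hybridInfo$hybridId)
  new("HybridCodes", hybridInfo = x@hybridInfo[i, , drop = FALSE],
      zA = x@zA[i, , drop = FALSE], zD = x@zD[i, , drop = FALSE],
      imputed = x@imputed[i])
})

#' Prediction accuracy from ability and heritability
#'
#' Standardizes the prediction ability by the square root of the trial
#' heritability: accuracy = ability / sqrt(h2). Values above 1 (possible
#' with estimation error) are returned as-is with a \code{"capped"}
#' attribute flag.
#'
#' @param ability Pearson prediction ability.
#' @param h2 broad-sense heritability in (0, 1].
#' @return accuracy (numeric), with attribute \code{capped}.
#' @export
predictionAccuracy <- function(ability, h2) {
  if (any(h2 <= 0)) stop("heritability must be > 0")
  acc <- ability / sqrt(h2)
  attr(acc, "capped") <- acc > 1
  acc
}
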