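## Independent oracles used to cross-check the package implementations.

## Dense EM-REML for y = X b + sum_i Z_i u_i + e, u_i ~ N(0, s2_i I).
## Deliberately naive: direct matrix algebra, fixed-point EM updates.
emRemlOracle <- function(y, X, Zlist, tol = 1e-10, maxit = 50000) {
  n <- length(y)
  k <- length(Zlist)
  s2 <- rep(var(y) / (k + 1), k + 1)  # components then error
  q <- vapply(Zlist, ncol, numeric(1))
  for (it in seq_len(maxit)) {
    V <- diag(s2[k + 1], n)
    for (i in seq_len(k)) V <- V + s2[i] * tcrossprod(Zlist[[i]])
    Vi <- solve(V)
    XtViX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
    Py <- P %*% y
    new <- s2
    for (i in seq_len(k)) {
      Zi <- Zlist[[i]]
      new[i] <- s2[i] + s2[i]^2 *
        (crossprod(crossprod(Zi, Py)) - sum(diag(crossprod(Zi, P %*% Zi)))) / q[i]
    }
    new[k + 1] <- s2[k + 1] + s2[k + 1]^2 *
      (crossprod(Py) - sum(diag(P))) / n
    new <- pmax(new, 1e-12)
    if (max(abs(new - s2)) < tol) { s2 <- new; break }
    s2 <- new
  }
  s2
}

## closed-form ridge for a single centred predictor with intercept
ridgeOracle <- function(z, y, lambda) {
  zc <- z - mean(z)
  yc <- y - mean(y)
  sum(zc * yc) / (sum(zc^2) + lambda)
}

## GBLUP (kernel) solution of the additive+dominance ridge model;
## independent algebraic route to the MME solution.
gblupOracle <- function(zA, zD, y, lambdaA, lambdaD) {
  cA <- colMeans(zA); cD <- colMeans(zD)
  Za <- sweep(zA, 2, cA); Zd <- sweep(zD, 2, cD)
  n <- length(y)
  V <- diag(n) + tcrossprod(Za) / lambdaA + tcrossprod(Zd) / lambdaD
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  g <- (tcrossprod(Za) / lambdaA + tcrossprod(Zd) / lambdaD) %*%
    Vi %*% (y - mu)
  as.vector(mu + g)
}

## per-locus exhaustive enumeration of the selection limit: for each
## marker, enumerate every pair of fixable dosages and evaluate the
## F-infinity genotypic value directly.
selectionLimitOracle <- function(mu, a, d, dos1, dos2) {
  total <- 0
  for (j in seq_along(a)) {
    a1 <- unique(dos1[, j]); a1 <- a1[!is.na(a1)]
    a2 <- unique(dos2[, j]); a2 <- a2[!is.na(a2)]
    alleles <- function(v) unique(unlist(lapply(v, function(x)
      switch(as.character(x), "0" = 0, "1" = c(0, 2), "2" = 2))))
    a1 <- alleles(a1); a2 <- alleles(a2)
    if (!length(a1) || !length(a2)) next
    best <- -Inf
    for (x in a1) for (yy in a2) {
      val <- if (x == 2 && yy == 2) a[j] else if (x == 0 && yy == 0)
        -a[j] else d[j]
      best <- max(best, val)
    }
    total <- total + best
  }
  mu + total
}

## independent exhaustive enumeration of the best pattern (ordered loop,
## different traversal from bruteForceSearch)
enumeratePatternsOracle <- function(H, s) {
  ids <- rownames(H)
  n <- length(ids)
  best <- -Inf
  combs <- combn(n, s, simplify = FALSE)
  for (i in seq_along(combs)) {
    for (j in seq_along(combs)) {
      if (length(intersect(combs[[i]], combs[[j]]))) next
      sc <- mean(H[ids[combs[[i]]], ids[combs[[j]]]])
      if (sc > best) best <- sc
    }
  }
  best
}
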