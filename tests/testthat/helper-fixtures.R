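## Small in-code fixtures shared across test files.

toyGenotypes <- function(d, pool = NULL, ...) {
  if (is.null(rownames(d))) rownames(d) <- paste0("L", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- paste0("m", seq_len(ncol(d)))
  if (is.null(pool)) pool <- rep("male", nrow(d))
  GenotypeMatrix(d, pool = pool, ...)
}

## symmetric score matrix with named lines from a seed
randomScoreMatrix <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n))
  H <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  v <- rnorm(n * (n - 1) / 2)
  H[upper.tri(H)] <- v
  H[lower.tri(H)] <- t(H)[lower.tri(H)]
  H
}

## a small simulated program reused by several files (moderate noise)
smallProgram <- function(seed = 42, ...) {
  cfg <- simConfig(nMale = 14, nFemale = 4, nHybrids = 36, nMarkers = 150,
                   nQtl = 50, varGxL = 0.4, varError = 0.3, seed = seed,
                   ...)
  simulateProgram(cfg)
}
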