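#' Minor allele frequencies of a genotype panel
#'
#' Allele frequencies are computed from dosages across all non-missing lines
#' of the panel; the minor-allele frequency is min(p, 1 - p).
#'
#' @param g a [GenotypeMatrix-class].
#' @return named numeric vector of MAFs, one per marker.
#' @export
minorAlleleFreq <- function(g) {
  p <- colMeans(dosage(g), na.rm = TRUE) / 2
  setNames(pmin(p, 1 - p), markerIds(g))
}

#' Filter markers by minor allele frequency
#'
#' Keeps exactly the markers whose MAF across all non-missing lines is at
#' least \code{mafMin}; marker order is preserved. Filtering is idempotent.
#'
#' @param g a [GenotypeMatrix-class].
#' @param mafMin minimum minor-allele frequency in [0, 0.5]; the
#'   conventional panel QC threshold is 0.05.
#' @return the filtered [GenotypeMatrix-class].
#' @export
filterMarkers <- function(g, mafMin = 0.05) {
  stopifnot(is(g, "GenotypeMatrix"), nMarkers(g) > 0,
            mafMin >= 0, mafMin <= 0.5)
  keep <- minorAlleleFreq(g) >= mafMin
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop("empty panel: all markers removed by MAF filter at ", mafMin)
  g[, which(keep)]
}

#' Rogers' distance between all pairs of lines
#'
#' For each pair of lines, the per-locus term is the Euclidean distance of
#' allele-frequency vectors scaled by sqrt(1/2), averaged over loci
#' non-missing in both lines. For biallelic dosages this reduces to
#' |d_i - d_j| / 2 per locus; for fully homozygous inbreds it is the
#' fraction of loci at which the two lines carry different alleles.
#'
#' @param g a [GenotypeMatrix-class].
#' @return symmetric n x n matrix with zero diagonal, entries in [0, 1],
#'   dimnames = line ids.
#' @export
rogersDistance <- function(g) {
  x <- dosage(g) / 2
  n <- nrow(x)
  ids <- lineIds(g)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(n - 1, 0))) {
    xi <- x[i, ]
    for (j in seq.int(i + 1L, n)) {
      shared <- !is.na(xi) & !is.na(x[j, ])
      if (!any(shared))
        stop("lines ", ids[i], " and ", ids[j],
             " share no non-missing loci; Rogers' distance undefined")
      D[i, j] <- D[j, i] <- mean(abs(xi[shared] - x[j, shared]))
    }
  }
  D
}

#' Additive relationship from Rogers' distances
#'
#' The additive relationship between parental pairs is one minus their
#' Rogers' distance; the diagonal is 1.
#'
#' @param rd symmetric Rogers' distance matrix (entries in [0, 1]).
#' @return relationship matrix A = 1 - RD with unit diagonal.
#' @export
additiveRelationship <- function(rd) {
  stopifnot(is.matrix(rd), nrow(rd) == ncol(rd),
            all(abs(rd - t(rd)) < 1e-12), all(rd >= -1e-12 & rd <= 1 + 1e-12))
  A <- 1 - rd
  diag(A) <- 1
  A
}

#' Pairwise linkage disequilibrium r-squared
#'
#' r2 is the squared Pearson correlation of dosage vectors across lines
#' (complete cases per pair), computed for marker pairs on the same
#' chromosome within \code{maxDistBp} (positions are 1-based bp; distance
#' is |pos_i - pos_j|). For homozygous inbreds dosage correlation equals
#' the haplotype-level r. Pairs involving a marker monomorphic among the
#' complete cases are skipped with a message.
#'
#' @param g a [GenotypeMatrix-class] with marker positions.
#' @param maxDistBp maximum physical distance between pair members.
#' @return data.frame with columns marker1, marker2, distBp, r2.
#' @export
ldR2 <- function(g, maxDistBp = Inf) {
  mi <- markerMap(g)
  x <- dosage(g)
  out <- vector("list", 0L)
  skipped <- 0L
  for (chr in unique(mi$chrom)) {
    idx <- which(mi$chrom == chr)
    if (length(idx) < 2) next
    for (u in seq_len(length(idx) - 1L)) {
      for (v in seq.int(u + 1L, length(idx))) {
        i <- idx[u]; j <- idx[v]
        dbp <- abs(mi$pos[i] - mi$pos[j])
        if (dbp > maxDistBp) next
        cc <- complete.cases(x[, i], x[, j])
        vi <- x[cc, i]; vj <- x[cc, j]
        if (length(vi) < 2 || var(vi) == 0 || var(vj) == 0) {
          skipped <- skipped + 1L
          next
        }
        out[[length(out) + 1L]] <- data.frame(
          marker1 = mi$markerId[i], marker2 = mi$markerId[j],
          distBp = dbp, r2 = cor(vi, vj)^2, stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped > 0L)
    message(skipped, " marker pair(s) skipped: monomorphic marker, ",
            "correlation undefined")
  if (!length(out))
    return(data.frame(marker1 = character(), marker2 = character(),
                      distBp = numeric(), r2 = numeric()))
  do.call(rbind, out)
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling (Gower): the doubly centred -D^2/2 matrix is
#' eigendecomposed and coordinates are returned for the leading axes in
#' decreasing eigenvalue order. Negative eigenvalues (non-Euclidean
#' distances) are reported, never silently dropped. When the distance
#' matrix is Euclidean-embeddable the pairwise coordinate distances over
#' all positive axes reproduce the input exactly.
#'
#' @param d symmetric distance matrix (e.g. from [rogersDistance()]).
#' @param nAxes number of axes requested (>= 1). If it exceeds the number
#'   of positive eigenvalues the result is truncated with a warning.
#' @return list with \code{coordinates} (n x k matrix, k <= nAxes),
#'   \code{eigenvalues} (all n), \code{relEig} (shares of the positive
#'   eigenvalue total), and \code{negative} (the negative eigenvalues).
#' @export
runPcoa <- function(d, nAxes = 2) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nAxes >= 1)
  n <- nrow(d)
  fit <- cmdscale(as.dist(d), k = max(1L, min(nAxes, n - 1L)), eig = TRUE)
  eig <- fit$eig
  npos <- sum(eig > 1e-9)
  k <- min(nAxes, max(npos, 0L))
  if (nAxes > npos) {
    warning("requested ", nAxes, " axes but only ", npos,
            " positive eigenvalues; returning ", k)
  }
  coords <- fit$points
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  if (k == 0L) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(d), "Axis1"))
    k <- 1L
  } else {
    coords <- coords[, seq_len(min(k, ncol(coords))), drop = FALSE]
    colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  }
  pos <- eig[eig > 1e-9]
  list(coordinates = coords,
       eigenvalues = eig,
       relEig = if (length(pos)) pos / sum(pos) else numeric(0),
       negative = eig[eig < -1e-9])
}

## F-infinity coding of one parental dosage pair (vectorised over markers).
## Returns list(zA, zD) with NA where either parent is missing.
.codeOnePair <- function(df, dm) {
  pf <- df / 2
  pm <- dm / 2
  zA <- pf + pm - 1
  zD <- pf * (1 - pm) + (1 - pf) * pm
  list(zA = zA, zD = zD)
}

#' F-infinity covariates for one hybrid
#'
#' Codes a single cross from its two parental dosage vectors: parents both
#' homozygous for the reference allele give (z_A, z_D) = (+1, 0), both for
#' the alternative (-1, 0), and discordant homozygotes (0, 1). Missing
#' parental calls yield NA covariates (mean-imputed at the set level by
#' [codeHybrids()]). Heterozygous parental calls are an error unless
#' \code{allowHet}, in which case expected covariates under Mendelian
#' sampling are used.
#'
#' @param female,male numeric dosage vectors (0/1/2/NA) of the two parents.
#' @param allowHet tolerate heterozygous parental calls (impure lines).
#' @param femaleId,maleId ids used in error messages.
#' @return list with elements \code{zA} and \code{zD}.
#' @export
codeHybrid <- function(female, male, allowHet = FALSE,
                       femaleId = "female", maleId = "male") {
  stopifnot(length(female) == length(male))
  if (!allowHet) {
    for (nm in c("femaleId", "maleId")) {
      v <- if (nm == "femaleId") female else male
      het <- which(!is.na(v) & v == 1)
      if (length(het)) {
        mk <- if (!is.null(names(v))) names(v)[het[1]] else het[1]
        stop("heterozygous call for line ",
             if (nm == "femaleId") femaleId else maleId,
             " at marker ", mk, "; set allowHet = TRUE for impure lines")
      }
    }
  }
  .codeOnePair(female, male)
}

#' F-infinity covariates for a set of crosses
#'
#' Builds the Z_A and Z_D design-matrix rows for every cross in
#' \code{crosses} from the parental [GenotypeMatrix-class]. Covariates
#' undefined because of missing parental calls are imputed with the
#' column (marker) mean over the coded hybrids; the number of imputed
#' entries is recorded per hybrid.
#'
#' @param g parental [GenotypeMatrix-class].
#' @param crosses data.frame with columns hybridId, femaleId, maleId.
#' @return a [HybridCodes-class].
#' @export
codeHybrids <- function(g, crosses) {
  stopifnot(all(c("hybridId", "femaleId", "maleId") %in% names(crosses)))
  miss <- setdiff(unique(c(crosses$femaleId, crosses$maleId)), lineIds(g))
  if (length(miss))
    stop("parents not genotyped: ", paste(head(miss, 5), collapse = ", "))
  d <- dosage(g)
  n <- nrow(crosses)
  m <- ncol(d)
  zA <- matrix(NA_real_, n, m, dimnames = list(crosses$hybridId, colnames(d)))
  zD <- zA
  for (h in seq_len(n)) {
    cd <- codeHybrid(d[crosses$femaleId[h], ], d[crosses$maleId[h], ],
                     allowHet = g@allowHet,
                     femaleId = crosses$femaleId[h],
                     maleId = crosses$maleId[h])
    zA[h, ] <- cd$zA
    zD[h, ] <- cd$zD
  }
  imputed <- integer(n)
  nas <- is.na(zA)
  if (any(nas)) {
    imputed <- as.integer(rowSums(nas))
    mA <- colMeans(zA, na.rm = TRUE)
    mD <- colMeans(zD, na.rm = TRUE)
    mA[is.nan(mA)] <- 0
    mD[is.nan(mD)] <- 0
    idx <- which(nas, arr.ind = TRUE)
    zA[idx] <- mA[idx[, 2]]
    zD[idx] <- mD[idx[, 2]]
  }
  new("HybridCodes",
      hybridInfo = data.frame(hybridId = as.character(crosses$hybridId),
                              femaleId = as.character(crosses$femaleId),
                              maleId = as.character(crosses$maleId),
                              stringsAsFactors = FALSE),
      zA = zA, zD = zD, imputed = imputed)
}
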