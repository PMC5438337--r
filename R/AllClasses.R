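#' @import methods
#' @importFrom stats var cor sd rnorm runif rbinom rgamma cmdscale optim
#'   pchisq logLik as.formula setNames aggregate quantile complete.cases
#'   na.omit coef
#' @importFrom utils combn read.csv write.csv head
NULL

#' GenotypeMatrix: allele dosages of inbred parental lines
#'
#' Container for a lines x markers allele-dosage matrix of (essentially)
#' homozygous inbred lines, together with per-line metadata (pool membership,
#' market segment) and a physical marker map. Dosages are coded 0/2 for the
#' two homozygous states; 1 (heterozygous call) is only permitted when the
#' object was built with \code{allowHet = TRUE}, flagging impure lines.
#'
#' @slot dosage numeric matrix, lines x markers, entries in {0, 1, 2, NA}.
#' @slot lineInfo data.frame with columns \code{lineId}, \code{pool}
#'   (\code{"male"} or \code{"female"}), \code{segment}.
#' @slot markerInfo data.frame with columns \code{markerId}, \code{chrom},
#'   \code{pos} (1-based physical position in bp).
#' @slot allowHet logical; if TRUE, dosage 1 entries are tolerated.
#'
#' @seealso [GenotypeMatrix()] for the constructor.
#' @export
setClass("GenotypeMatrix",
  representation(
    dosage = "matrix",
    lineInfo = "data.frame",
    markerInfo = "data.frame",
    allowHet = "logical"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosage
  li <- object@lineInfo
  mi <- object@markerInfo
  if (nrow(d) != nrow(li)) msg <- c(msg, "lineInfo rows must match dosage rows")
  if (ncol(d) != nrow(mi)) msg <- c(msg, "markerInfo rows must match dosage columns")
  if (!all(c("lineId", "pool", "segment") %in% names(li)))
    msg <- c(msg, "lineInfo needs columns lineId, pool, segment")
  if (!all(c("markerId", "chrom", "pos") %in% names(mi)))
    msg <- c(msg, "markerInfo needs columns markerId, chrom, pos")
  if (anyDuplicated(li$lineId)) msg <- c(msg, "line ids must be unique")
  if (anyDuplicated(mi$markerId)) msg <- c(msg, "marker ids must be unique")
  ok <- d[!is.na(d)]
  allowed <- if (isTRUE(object@allowHet)) c(0, 1, 2) else c(0, 2)
  if (length(ok) && !all(ok %in% allowed))
    msg <- c(msg, sprintf("dosage entries must be in {%s} (or NA)",
                          paste(allowed, collapse = ", ")))
  if (!all(li$pool %in% c("male", "female")))
    msg <- c(msg, "pool labels must be 'male' or 'female'")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage lines x markers numeric matrix with entries 0/1/2/NA. Row
#'   names are taken as line ids and column names as marker ids when the
#'   corresponding id arguments are missing.
#' @param pool character vector of pool labels ("male"/"female"), one per line.
#' @param segment character scalar or per-line vector of segment labels.
#' @param chrom,pos marker map: chromosome labels and 1-based bp positions.
#' @param lineIds,markerIds optional explicit ids.
#' @param allowHet allow heterozygous (dosage 1) calls for impure lines.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' d <- rbind(L1 = c(0, 2, 2), L2 = c(2, 2, 0))
#' colnames(d) <- paste0("m", 1:3)
#' g <- GenotypeMatrix(d, pool = c("female", "male"), segment = "S1",
#'                     chrom = c(1, 1, 2), pos = c(100, 200, 50))
#' nLines(g)
#' @export
GenotypeMatrix <- function(dosage, pool, segment = "S1", chrom = NULL,
                           pos = NULL, lineIds = rownames(dosage),
                           markerIds = colnames(dosage), allowHet = FALSE) {
  dosage <- as.matrix(dosage)
  if (is.null(lineIds)) lineIds <- paste0("L", seq_len(nrow(dosage)))
  if (is.null(markerIds)) markerIds <- paste0("M", seq_len(ncol(dosage)))
  if (is.null(chrom)) chrom <- rep(1L, ncol(dosage))
  if (is.null(pos)) pos <- seq_len(ncol(dosage))
  rownames(dosage) <- lineIds
  colnames(dosage) <- markerIds
  li <- data.frame(lineId = as.character(lineIds),
                   pool = rep_len(as.character(pool), nrow(dosage)),
                   segment = rep_len(as.character(segment), nrow(dosage)),
                   stringsAsFactors = FALSE)
  mi <- data.frame(markerId = as.character(markerIds),
                   chrom = rep_len(chrom, ncol(dosage)),
                   pos = as.numeric(rep_len(pos, ncol(dosage))),
                   stringsAsFactors = FALSE)
  new("GenotypeMatrix", dosage = dosage, lineInfo = li, markerInfo = mi,
      allowHet = isTRUE(allowHet))
}

#' @describeIn GenotypeMatrix Number of lines.
#' @param x,object a GenotypeMatrix.
#' @export
nLines <- function(x) nrow(x@dosage)

#' @describeIn GenotypeMatrix Number of markers.
#' @export
nMarkers <- function(x) ncol(x@dosage)

#' @describeIn GenotypeMatrix Line ids.
#' @export
lineIds <- function(x) x@lineInfo$lineId

#' @describeIn GenotypeMatrix Marker ids.
#' @export
markerIds <- function(x) x@markerInfo$markerId

#' @describeIn GenotypeMatrix Dosage matrix (lines x markers).
#' @export
dosage <- function(x) x@dosage

#' @describeIn GenotypeMatrix Named vector of pool labels.
#' @export
pools <- function(x) setNames(x@lineInfo$pool, x@lineInfo$lineId)

#' @describeIn GenotypeMatrix Marker map data.frame.
#' @export
markerMap <- function(x) x@markerInfo

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nLines(object), "lines x", nMarkers(object),
      "markers\n")
  tb <- table(object@lineInfo$pool)
  cat("  pools:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  nmiss <- sum(is.na(object@dosage))
  cat("  missing calls:", nmiss,
      sprintf("(%.2f%%)\n", 100 * nmiss / length(object@dosage)))
})

#' Subset a GenotypeMatrix by lines and/or markers
#'
#' @param x a GenotypeMatrix
#' @param i line indices or ids
#' @param j marker indices or ids
#' @param ... ignored
#' @param drop ignored; always returns a GenotypeMatrix
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nLines(x))
  if (missing(j)) j <- seq_len(nMarkers(x))
  if (is.character(i)) i <- match(i, lineIds(x))
  if (is.character(j)) j <- match(j, markerIds(x))
  new("GenotypeMatrix",
      dosage = x@dosage[i, j, drop = FALSE],
      lineInfo = x@lineInfo[i, , drop = FALSE],
      markerInfo = x@markerInfo[j, , drop = FALSE],
      allowHet = x@allowHet)
})

#' HybridCodes: F-infinity marker covariates of single-cross hybrids
#'
#' Rows of the additive (Z_A) and dominance (Z_D) design matrices for a set
#' of hybrids, derived from the two homozygous parents per cross under the
#' F-infinity metric: both parents carrying the reference homozygote gives
#' z_A = +1, both the alternative gives z_A = -1, and discordant homozygotes
#' give z_A = 0 with z_D = 1.
#'
#' @slot hybridInfo data.frame with columns hybridId, femaleId, maleId.
#' @slot zA hybrids x markers additive covariates in [-1, 1].
#' @slot zD hybrids x markers dominance covariates in [0, 1].
#' @slot imputed integer count of mean-imputed marker covariates per hybrid.
#' @export
setClass("HybridCodes",
  representation(
    hybridInfo = "data.frame",
    zA = "matrix",
    zD = "matrix",
    imputed = "integer"
  )
)

setValidity("HybridCodes", function(object) {
  msg <- character()
  if (nrow(object@zA) != nrow(object@hybridInfo) ||
      nrow(object@zD) != nrow(object@hybridInfo))
    msg <- c(msg, "zA/zD rows must match hybridInfo")
  if (!identical(dim(object@zA), dim(object@zD)))
    msg <- c(msg, "zA and zD must have identical dimensions")
  if (anyDuplicated(object@hybridInfo$hybridId))
    msg <- c(msg, "hybrid ids must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn HybridCodes Additive covariate matrix.
#' @param x a HybridCodes object.
#' @export
zAdditive <- function(x) x@zA

#' @describeIn HybridCodes Dominance covariate matrix.
#' @export
zDominance <- function(x) x@zD

#' @describeIn HybridCodes Hybrid metadata (hybridId, femaleId, maleId).
#' @export
hybridInfo <- function(x) x@hybridInfo

setMethod("show", "HybridCodes", function(object) {
  cat("HybridCodes:", nrow(object@zA), "hybrids x", ncol(object@zA),
      "markers\n")
  cat("  mean-imputed covariates:", sum(object@imputed), "\n")
})

#' VarianceComponents: REML estimates from a hybrid trial model
#'
#' Named REML variance-component estimates together with the trial context
#' (number of locations and within-location replicates) needed to evaluate
#' broad-sense heritability on an entry-mean basis.
#'
#' @slot sigma2 named numeric vector of variance components.
#' @slot nLocations integer, locations in the data.
#' @slot nReplicates integer, effective replicates per location (1 for
#'   unreplicated entries in augmented designs).
#' @slot logLik REML log-likelihood of the fit.
#' @slot converged logical convergence flag.
#' @slot boundary names of components estimated at (or within 1e-8 of) zero.
#' @slot model character label of the fitted model.
#' @export
setClass("VarianceComponents",
  representation(
    sigma2 = "numeric",
    nLocations = "integer",
    nReplicates = "integer",
    logLik = "numeric",
    converged = "logical",
    boundary = "character",
    model = "character"
  )
)

setValidity("VarianceComponents", function(object) {
  if (any(object@sigma2 < -1e-8, na.rm = TRUE))
    "variance components must be non-negative" else TRUE
})

#' @describeIn VarianceComponents Named variance-component vector.
#' @param x a VarianceComponents object.
#' @export
sigma2 <- function(x) x@sigma2

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (", object@model, ")\n", sep = "")
  print(round(object@sigma2, 4))
  cat("  locations:", object@nLocations,
      " replicates:", object@nReplicates,
      " REML logLik:", round(object@logLik, 3), "\n")
  if (length(object@boundary))
    cat("  at boundary:", paste(object@boundary, collapse = ", "), "\n")
})

#' MarkerEffects: RR-BLUP intercept and per-marker effects
#'
#' Solution of Henderson's mixed-model equations for the additive +
#' dominance RR-BLUP model. The intercept is expressed on the raw covariate
#' scale, so predictions are mu + zA %*% a + zD %*% d for uncentred codes.
#'
#' @slot mu intercept on the raw-code scale.
#' @slot a named additive effects per marker.
#' @slot d named dominance effects per marker.
#' @slot lambdaA,lambdaD shrinkage ratios sigma2_e / sigma2_a (resp. _d).
#' @export
setClass("MarkerEffects",
  representation(
    mu = "numeric",
    a = "numeric",
    d = "numeric",
    lambdaA = "numeric",
    lambdaD = "numeric"
  )
)

setValidity("MarkerEffects", function(object) {
  msg <- character()
  if (length(object@a) != length(object@d))
    msg <- c(msg, "a and d must have equal length")
  if (object@lambdaA <= 0 || object@lambdaD <= 0)
    msg <- c(msg, "shrinkage ratios must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MarkerEffects", function(object) {
  cat("MarkerEffects:", length(object@a), "markers\n")
  cat(sprintf("  mu = %.4f  lambda_a = %.4g  lambda_d = %.4g\n",
              object@mu, object@lambdaA, object@lambdaD))
})

#' HeteroticPattern: a matched pair of heterotic groups
#'
#' Two disjoint, equal-size sets of parental lines together with the score
#' that drove the search: the mean predicted performance over all
#' inter-group single crosses.
#'
#' @slot group1,group2 character vectors of line ids (disjoint, equal size).
#' @slot score mean predicted inter-group hybrid performance.
#' @slot size group size s.
#' @slot metadata list with search provenance (seed, schedule, iterations,
#'   acceptance counts, method).
#' @export
setClass("HeteroticPattern",
  representation(
    group1 = "character",
    group2 = "character",
    score = "numeric",
    size = "integer",
    metadata = "list"
  )
)

setValidity("HeteroticPattern", function(object) {
  msg <- character()
  if (length(object@group1) != length(object@group2))
    msg <- c(msg, "groups must have equal size")
  if (length(intersect(object@group1, object@group2)))
    msg <- c(msg, "groups must be disjoint")
  if (length(object@group1) != object@size)
    msg <- c(msg, "size slot must match group length")
  if (!is.finite(object@score)) msg <- c(msg, "score must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn HeteroticPattern Score (mean inter-group prediction).
#' @param x a HeteroticPattern.
#' @export
patternScoreValue <- function(x) x@score

#' @describeIn HeteroticPattern Member ids as a list of the two groups.
#' @export
patternGroups <- function(x) list(group1 = x@group1, group2 = x@group2)

setMethod("show", "HeteroticPattern", function(object) {
  cat("HeteroticPattern: size", object@size,
      " score", round(object@score, 4), "\n")
  cat("  group1:", paste(object@group1, collapse = ", "), "\n")
  cat("  group2:", paste(object@group2, collapse = ", "), "\n")
})
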