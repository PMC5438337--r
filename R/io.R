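#' Read parental genotypes from CSV
#'
#' Expects a matrix CSV (first column = line id, remaining columns =
#' markers, values 0/1/2/NA), an optional marker map CSV with columns
#' \code{marker}, \code{chrom}, \code{pos} (1-based bp) and an optional
#' line metadata CSV with columns \code{line_id}, \code{pool},
#' \code{segment}.
#'
#' @param path genotype matrix CSV.
#' @param mapPath marker map CSV (defaults: one chromosome, index
#'   positions).
#' @param metaPath line metadata CSV (default: all lines labelled male).
#' @param allowHet tolerate heterozygous calls.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypesCsv <- function(path, mapPath = NULL, metaPath = NULL,
                             allowHet = FALSE) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("genotype CSV needs a line-id column plus markers")
  ids <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  rownames(d) <- ids
  chrom <- rep(1L, ncol(d)); pos <- seq_len(ncol(d))
  if (!is.null(mapPath)) {
    mp <- read.csv(mapPath, stringsAsFactors = FALSE)
    idx <- match(colnames(d), mp$marker)
    if (any(is.na(idx))) stop("marker map lacks ",
                              sum(is.na(idx)), " marker(s)")
    chrom <- mp$chrom[idx]; pos <- mp$pos[idx]
  }
  pool <- rep("male", nrow(d)); segment <- "S1"
  if (!is.null(metaPath)) {
    mt <- read.csv(metaPath, stringsAsFactors = FALSE)
    idx <- match(ids, mt$line_id)
    if (any(is.na(idx))) stop("line metadata lacks ",
                              sum(is.na(idx)), " line(s)")
    pool <- mt$pool[idx]; segment <- mt$segment[idx]
  }
  GenotypeMatrix(d, pool = pool, segment = segment, chrom = chrom,
                 pos = pos, allowHet = allowHet)
}

#' Read parental genotypes from VCF
#'
#' Biallelic SNPs with a GT field; samples are the parental lines. GT is
#' converted to alternate-allele dosage (0/1/2; missing calls to NA).
#'
#' @param path VCF file (plain or gzipped).
#' @param metaPath optional line metadata CSV (line_id, pool, segment).
#' @param allowHet tolerate heterozygous calls.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypesVcf <- function(path, metaPath = NULL, allowHet = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readGenotypesVcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  conv <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% c("0/0")] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x %in% c("1/1")] <- 2
    out
  }
  d <- t(apply(gt, 2, conv))
  colnames(d) <- rownames(gt)
  rownames(d) <- colnames(gt)
  fix <- vcfR::getFIX(v)
  pool <- rep("male", nrow(d)); segment <- "S1"
  if (!is.null(metaPath)) {
    mt <- read.csv(metaPath, stringsAsFactors = FALSE)
    idx <- match(rownames(d), mt$line_id)
    if (any(is.na(idx))) stop("line metadata lacks ",
                              sum(is.na(idx)), " line(s)")
    pool <- mt$pool[idx]; segment <- mt$segment[idx]
  }
  GenotypeMatrix(d, pool = pool, segment = segment,
                 chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                 markerIds = make.unique(ifelse(is.na(fix[, "ID"]) |
                                                  fix[, "ID"] == ".",
                                                paste0(fix[, "CHROM"], "_",
                                                       fix[, "POS"]),
                                                fix[, "ID"])),
                 allowHet = allowHet)
}

#' Read a plot-record table from CSV
#'
#' @param path CSV with columns genotypeId, type, femaleId, maleId,
#'   locationId, trialId, blockId, maturityClass, yield.
#' @return a validated plot-record data.frame.
#' @export
readPlotRecords <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  .checkRecords(rec)
  rec
}

#' Read a cross list from CSV
#' @param path CSV with columns hybridId, femaleId, maleId.
#' @return data.frame.
#' @export
readCrossList <- function(path) {
  cr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("hybridId", "femaleId", "maleId")
  miss <- setdiff(need, names(cr))
  if (length(miss)) stop("cross list lacks columns: ",
                         paste(miss, collapse = ", "))
  cr
}

#' Write a square id-labelled matrix as CSV
#' @param m matrix with dimnames.
#' @param path output CSV path (header row and id column).
#' @export
writeMatrixCsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a GenotypeMatrix to the CSV formats the readers consume
#' @param g a [GenotypeMatrix-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
writeGenotypesCsv <- function(g, dir, prefix = "genotypes") {
  gp <- file.path(dir, paste0(prefix, ".csv"))
  mp <- file.path(dir, paste0(prefix, "_map.csv"))
  lp <- file.path(dir, paste0(prefix, "_lines.csv"))
  write.csv(data.frame(line_id = lineIds(g), dosage(g),
                       check.names = FALSE), gp, row.names = FALSE)
  mm <- markerMap(g)
  write.csv(data.frame(marker = mm$markerId, chrom = mm$chrom,
                       pos = mm$pos), mp, row.names = FALSE)
  write.csv(data.frame(line_id = lineIds(g), pool = g@lineInfo$pool,
                       segment = g@lineInfo$segment), lp, row.names = FALSE)
  invisible(c(gp, mp, lp))
}
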