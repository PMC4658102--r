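#' Genotype matrix container
#'
#' Holds an individuals-by-loci dosage matrix (minor/alternate allele counts
#' coded 0, 1, 2, with \code{NA} for missing calls) together with per-locus
#' metadata: chromosome, position, id, minor allele frequency, missing rate
#' and a per-locus quality score in \[0, 1\] (generalizing array calling
#' scores such as Illumina's GenTrain).
#'
#' @param dosage numeric matrix, individuals in rows, loci in columns.
#'   Row names are individual ids, column names locus ids (generated when
#'   absent).
#' @param locus_meta optional data.frame with columns \code{id},
#'   \code{chrom}, \code{pos}, \code{maf}, \code{missing_rate},
#'   \code{quality_score}. Missing columns are computed from the dosages
#'   (maf, missing rate) or defaulted (quality 1, chrom "1", pos = index).
#'
#' @return an object of class \code{genotype_matrix}: a list with elements
#'   \code{dosage} and \code{locus_meta}.
#' @export
genotype_matrix <- function(dosage, locus_meta = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("ind_%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("snp_%05d", seq_len(ncol(dosage)))
  if (anyDuplicated(rownames(dosage))) stop("individual ids must be unique")
  if (anyDuplicated(colnames(dosage))) stop("locus ids must be unique")

  m <- ncol(dosage)
  meta <- data.frame(id = colnames(dosage), stringsAsFactors = FALSE)
  if (!is.null(locus_meta)) {
    locus_meta <- as.data.frame(locus_meta)
    for (cn in setdiff(names(locus_meta), "id")) meta[[cn]] <- locus_meta[[cn]]
  }
  if (is.null(meta$chrom)) meta$chrom <- "1"
  if (is.null(meta$pos)) meta$pos <- seq_len(m)
  p <- colMeans(dosage, na.rm = TRUE) / 2
  if (is.null(meta$maf)) meta$maf <- pmin(p, 1 - p)
  if (is.null(meta$missing_rate)) meta$missing_rate <- colMeans(is.na(dosage))
  if (is.null(meta$quality_score)) meta$quality_score <- 1
  stopifnot(all(meta$maf >= 0 & meta$maf <= 0.5, na.rm = TRUE),
            all(meta$missing_rate >= 0 & meta$missing_rate <= 1))
  structure(list(dosage = dosage, locus_meta = meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param x a \code{genotype_matrix}
#' @param i individual index (any matrix row index)
#' @param j locus index
#' @param ... unused
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  d <- x$dosage[i, j, drop = FALSE]
  jj <- match(colnames(d), x$locus_meta$id)
  genotype_matrix(d, x$locus_meta[jj, , drop = FALSE])
}

## Deterministic sub-seed for a named generator stream.  Each generator
## derives its own stream from the user seed so modules can be re-run (and
## tested) independently without sharing RNG state.
split_seed <- function(seed, stream) {
  offsets <- c(island = 1L, ibd = 2L, clinal = 3L, climate = 4L,
               phenotypes = 5L, null = 6L, coalescent = 7L, dedup = 8L,
               perm = 9L, hotspot = 10L)
  off <- offsets[[stream]]
  (as.integer(seed) %% 1000003L) * 2011L + off * 7919L
}
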