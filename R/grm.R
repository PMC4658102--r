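#' SNP quality-control filter
#'
#' Retains loci passing all three array-style filters: minor allele
#' frequency at least \code{maf_min}, missing rate at most
#' \code{missing_max}, and per-locus quality score at least
#' \code{quality_min}. All thresholds are boundary-inclusive for retention
#' (a locus exactly at MAF 0.05, 10\% missing or score 0.5 is kept), since
#' the removal rules are strict inequalities. Locus order is preserved.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min,missing_max,quality_min filter thresholds (defaults 0.05,
#'   0.10, 0.5).
#' @param verbose log per-criterion failure counts.
#' @return the filtered \code{genotype_matrix}.
#' @export
qc_filter_snps <- function(g, maf_min = 0.05, missing_max = 0.10,
                           quality_min = 0.5, verbose = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  meta <- g$locus_meta
  fail_maf <- meta$maf < maf_min
  fail_mis <- meta$missing_rate > missing_max
  fail_q <- meta$quality_score < quality_min
  keep <- !(fail_maf | fail_mis | fail_q)
  if (!any(keep)) {
    stop(sprintf(
      "QC removed every locus (failed MAF: %d, missing: %d, quality: %d)",
      sum(fail_maf), sum(fail_mis), sum(fail_q)))
  }
  if (verbose)
    message(sprintf(
      "QC: kept %d/%d loci (failed MAF: %d, missing: %d, quality: %d)",
      sum(keep), length(keep), sum(fail_maf), sum(fail_mis), sum(fail_q)))
  g[, which(keep)]
}

#' Realized additive (genomic) relationship matrix
#'
#' VanRaden-type GRM from dosages: G = Z Z' / (2 sum p (1 - p)) with
#' Z = M - P, M the 0/1/2 dosage matrix and P the row of doubled observed
#' allele frequencies. Monomorphic loci are excluded (they carry no
#' relationship information and would not change Z), and missing dosages are
#' mean-imputed per locus (2p) before centering. If the result has a
#' negative smallest eigenvalue a small ridge (1e-6 x mean diagonal) is
#' added so downstream REML stays solvable; the amount is recorded.
#'
#' @param g a [genotype_matrix()].
#' @return an object of class \code{grm}: list with \code{G} (symmetric
#'   n x n), \code{ridge_applied}, \code{loci_used}, \code{n_monomorphic}.
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  M <- g$dosage
  p <- colMeans(M, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (sum(poly) < 2) stop("zero denominator: fewer than 2 polymorphic loci")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  # mean imputation, then center by 2p
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- 2 * p[idx[, 2]]
  }
  Z <- sweep(M, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  ridge <- 0
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0) {
    ridge <- 1e-6 * mean(diag(G))
    G <- G + diag(ridge, nrow(G))
  }
  structure(list(G = G, ridge_applied = ridge, loci_used = sum(poly),
                 n_monomorphic = sum(!poly)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d from %d loci (%d monomorphic excluded, ridge %g)\n",
              nrow(x$G), ncol(x$G), x$loci_used, x$n_monomorphic,
              x$ridge_applied))
  invisible(x)
}
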