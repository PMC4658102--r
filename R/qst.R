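#' Q_ST, heritability and P_ST from REML variance components
#'
#' These helpers turn fitted variance components into the standardized
#' differentiation ratios used throughout the pipeline. Narrow-sense Q_ST is
#' sigma2_p / (sigma2_p + 2 sigma2_a) from the animal model (cluster random
#' effect + GRM additive effect); broad-sense Q_ST replaces the additive
#' variance by the total (clonal) genetic variance from replicated ramets;
#' P_ST is the phenotypic analogue sigma2_p / (sigma2_p + 2 h2 sigma2_e).
#' Standard errors come from the delta method applied to the asymptotic
#' covariance of the component estimates.
#'
#' @name qst
NULL

qst_ratio <- function(vc, i_num, i_den, den_extra, kind, d) {
  sp <- vc$estimates[[i_num]]
  sa <- vc$estimates[[i_den]]
  degenerate <- (sp + den_extra * sa) <= 0
  value <- if (degenerate) NA_real_ else sp / (sp + den_extra * sa)
  se <- NA_real_
  V <- vc$vcov[c(i_num, i_den), c(i_num, i_den)]
  if (!degenerate && !anyNA(V)) {
    gr <- c(den_extra * sa, -den_extra * sp) / (sp + den_extra * sa)^2
    se <- sqrt(drop(t(gr) %*% V %*% gr))
  }
  structure(list(value = min(max(value, 0), 1), se = se, kind = kind,
                 d = d, degenerate = degenerate,
                 converged = vc$converged),
            class = "qst_estimate")
}

#' @rdname qst
#' @param vc a \code{varcomp} from [reml_fit()] of the animal model, with
#'   components named \code{cluster}, \code{additive}, \code{residual}.
#' @param d number of clusters the among-group variance was estimated over.
#' @return a \code{qst_estimate}: value in \[0, 1\], delta-method SE, kind,
#'   d, and a degenerate flag (both variances zero).
#' @export
narrow_qst <- function(vc, d) {
  stopifnot(inherits(vc, "varcomp"),
            all(c("cluster", "additive") %in% names(vc$estimates)))
  qst_ratio(vc, "cluster", "additive", 2, "narrow", d)
}

#' @rdname qst
#' @export
broad_qst <- function(vc, d) {
  stopifnot(inherits(vc, "varcomp"),
            all(c("cluster", "clone") %in% names(vc$estimates)))
  qst_ratio(vc, "cluster", "clone", 2, "broad", d)
}

#' @export
print.qst_estimate <- function(x, ...) {
  cat(sprintf("%s-sense estimate: %.4f (SE %s, d = %d)%s\n", x$kind, x$value,
              ifelse(is.na(x$se), "-", sprintf("%.4f", x$se)), x$d,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

## Align a phenotype table (genotype_id, ramet, trait) with a genotype order
pheno_design <- function(phenos, genotype_ids, trait = "trait") {
  stopifnot(all(phenos$genotype_id %in% genotype_ids))
  y <- phenos[[trait]]
  Zg <- incidence(factor(phenos$genotype_id, levels = genotype_ids))
  list(y = y, Zg = Zg)
}

#' Fit the animal model and compute narrow-sense Q_ST
#'
#' Convenience wrapper: builds the mixed model y = mu + cluster + additive +
#' residual with the cluster effect identity-covariate and the additive
#' effect covariated by the supplied GRM, REML-fits it, and returns the
#' components and the narrow-sense Q_ST.
#'
#' @param phenos data.frame with \code{genotype_id}, \code{ramet} and a
#'   trait column.
#' @param G a [compute_grm()] result (or plain PSD matrix) whose row order
#'   defines genotype order; row names are the genotype ids.
#' @param clusters cluster labels, one per genotype (G order).
#' @param trait trait column name.
#' @param ... passed to [reml_fit()].
#' @return list with \code{vc} (varcomp) and \code{qst} (qst_estimate).
#' @export
fit_narrow_qst <- function(phenos, G, clusters, trait = "trait", ...) {
  if (inherits(G, "grm")) G <- G$G
  gids <- rownames(G) %||% as.character(seq_len(nrow(G)))
  pd <- pheno_design(phenos, gids, trait)
  cl_of_obs <- clusters[match(phenos$genotype_id, gids)]
  spec <- mm_spec(pd$y, X = matrix(1, length(pd$y), 1),
                  random = list(cluster = list(Z = incidence(cl_of_obs)),
                                additive = list(Z = pd$Zg, K = G)))
  vc <- reml_fit(spec, ...)
  list(vc = vc, qst = narrow_qst(vc, d = length(unique(clusters))))
}

#' Fit the clonal-replication model and compute broad-sense Q_ST
#'
#' With replicated ramets the total genetic (clone) variance is estimable
#' without any relationship matrix: y = mu + cluster + clone + ramet
#' residual. Broad-sense Q_ST is sigma2_p / (sigma2_p + 2 sigma2_G) with
#' sigma2_G the clone variance. Requires genuine replication; with a single
#' ramet everywhere the clone and residual terms are confounded and the fit
#' is refused.
#'
#' @inheritParams fit_narrow_qst
#' @export
fit_broad_qst <- function(phenos, clusters, trait = "trait", ...) {
  gids <- unique(phenos$genotype_id)
  if (max(table(phenos$genotype_id)) < 2)
    stop("broad-sense Q_ST needs clonal replication (>= 2 ramets for some genotypes)")
  pd <- pheno_design(phenos, gids, trait)
  cl_of_obs <- clusters[match(phenos$genotype_id, gids)]
  spec <- mm_spec(pd$y, X = matrix(1, length(pd$y), 1),
                  random = list(cluster = list(Z = incidence(cl_of_obs)),
                                clone = list(Z = pd$Zg)))
  vc <- reml_fit(spec, ...)
  list(vc = vc, qst = broad_qst(vc, d = length(unique(clusters))))
}

#' Heritability and P_ST from the paired fixed-/random-cluster fits
#'
#' Two REML fits on the same data: (i) cluster as a fixed effect with a
#' GRM-covariated additive term, giving narrow-sense heritability
#' h2 = sigma2_a / (sigma2_a + sigma2_e); (ii) cluster as the only random
#' effect (individuals within cluster absorbed into the error), giving
#' sigma2_p and sigma2_e. P_ST is then assembled as
#' sigma2_p / (sigma2_p + 2 h2 sigma2_e), deliberately combining h2 from the
#' first fit with the second fit's variances — the two fits' residuals
#' differ in meaning, and the ratio is reported exactly as defined, flagged
#' degenerate when h2 = 0 (P_ST pinned at 1 for any positive sigma2_p).
#'
#' @inheritParams fit_narrow_qst
#' @return list with \code{h2} and \code{pst} (both \code{qst_estimate}-shaped)
#'   plus the two underlying \code{varcomp} fits.
#' @export
h2_pst <- function(phenos, G, clusters, trait = "trait", ...) {
  if (inherits(G, "grm")) G <- G$G
  gids <- rownames(G) %||% as.character(seq_len(nrow(G)))
  pd <- pheno_design(phenos, gids, trait)
  cl_of_obs <- clusters[match(phenos$genotype_id, gids)]
  d <- length(unique(clusters))

  X5 <- cbind(1, incidence(cl_of_obs)[, -1, drop = FALSE])
  spec5 <- mm_spec(pd$y, X5,
                   random = list(additive = list(Z = pd$Zg, K = G)))
  vc5 <- reml_fit(spec5, ...)
  h2 <- qst_ratio(vc5, "additive", "residual", 1, "h2", d)

  spec8 <- mm_spec(pd$y, matrix(1, length(pd$y), 1),
                   random = list(cluster = list(Z = incidence(cl_of_obs))))
  vc8 <- reml_fit(spec8, ...)

  sp <- vc8$estimates[["cluster"]]
  se2 <- vc8$estimates[["residual"]]
  h2v <- h2$value
  degenerate <- (h2v <= 0 && sp > 0) || (sp + 2 * h2v * se2) <= 0
  pst_val <- if ((sp + 2 * h2v * se2) > 0) sp / (sp + 2 * h2v * se2)
             else NA_real_
  # delta method over (sp, se2) from fit (ii) and h2 from fit (i), the
  # three treated as independent across the two fits
  pst_se <- NA_real_
  V8 <- vc8$vcov[c("cluster", "residual"), c("cluster", "residual")]
  if (!is.na(pst_val) && !anyNA(V8) && !is.na(h2$se)) {
    den <- (sp + 2 * h2v * se2)^2
    gr <- c(2 * h2v * se2 / den, -2 * h2v * sp / den)
    g_h2 <- -2 * se2 * sp / den
    pst_se <- sqrt(drop(t(gr) %*% V8 %*% gr) + g_h2^2 * h2$se^2)
  }
  pst <- structure(list(value = min(max(pst_val, 0), 1), se = pst_se,
                        kind = "pst", d = d, degenerate = degenerate,
                        converged = vc5$converged && vc8$converged),
                   class = "qst_estimate")
  list(h2 = h2, pst = pst, vc_h2 = vc5, vc_cluster = vc8)
}
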