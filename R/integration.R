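#' Overlap of outlier calls across detection methods
#'
#' Venn-style accounting over named sets of SNP ids: the count of every
#' intersection cell (membership pattern) and, per method, the fraction of
#' its calls shared with at least one other method. Cell counts always sum
#' to the size of the union.
#'
#' Because "overlap among methods" admits two denominators, both overall
#' fractions are returned with explicit names: \code{shared_fraction_snps}
#' (flagged SNPs appearing in >= 2 methods, over the union of SNPs) and
#' \code{shared_fraction_calls} (method-SNP calls whose SNP appears in
#' >= 2 methods, over all calls).
#'
#' @param sets named list (>= 2) of character vectors of SNP ids.
#' @return list with \code{cells} (data.frame pattern, count),
#'   \code{shared_fraction} (per method), \code{shared_fraction_snps},
#'   \code{shared_fraction_calls}, \code{union_size}.
#' @export
method_overlap <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1) memb <- matrix(memb, nrow = 1,
                                           dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  cells <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(cells) <- c("pattern", "count")
  n_methods <- rowSums(memb)
  shared <- vapply(names(sets), function(nm) {
    mine <- memb[, nm]
    if (!any(mine)) return(NA_real_)
    mean(n_methods[mine] >= 2)
  }, 0)
  n_calls <- sum(lengths(sets))
  list(cells = cells, shared_fraction = shared,
       shared_fraction_snps = mean(n_methods >= 2),
       shared_fraction_calls = sum(n_methods[n_methods >= 2]) / n_calls,
       union_size = length(all_ids))
}

#' Adaptive-SNP report combining outliers, associations and trait verdicts
#'
#' A SNP enters the report when (i) at least one outlier-detection method
#' flagged it and (ii) it is associated with at least one adaptive trait (a
#' trait whose Q_ST significantly exceeded the neutral expectation). Each
#' row carries the set of flagging methods, whether the SNP is shared
#' (>= 2 methods) or unique (exactly 1), its associated traits, the
#' adaptive subset and the pleiotropy degree (number of distinct adaptive
#' traits). Association rows whose SNP is absent from the genotype panel
#' are excluded and logged.
#'
#' @param assoc data.frame with \code{snp_id}, \code{trait},
#'   \code{p_value}.
#' @param trait_verdicts named logical vector: trait -> adaptive flag; must
#'   cover every trait in \code{assoc}.
#' @param method_flags named list of character vectors of flagged SNP ids.
#' @param panel_snps character vector of valid SNP ids (the genotype
#'   panel); NULL skips the orphan check.
#' @return data.frame (possibly empty): snp, methods, n_methods, sharing,
#'   traits, adaptive_traits, pleiotropy.
#' @export
adaptive_snp_report <- function(assoc, trait_verdicts, method_flags,
                                panel_snps = NULL) {
  stopifnot(is.list(method_flags), length(method_flags) >= 1)
  if (nrow(assoc) == 0)
    return(data.frame(snp = character(0), methods = character(0),
                      n_methods = integer(0), sharing = character(0),
                      traits = character(0), adaptive_traits = character(0),
                      pleiotropy = integer(0), stringsAsFactors = FALSE))
  missing_traits <- setdiff(unique(assoc$trait), names(trait_verdicts))
  if (length(missing_traits) > 0)
    stop("no verdict for trait(s): ", paste(missing_traits, collapse = ", "))
  if (!is.null(panel_snps)) {
    orphan <- !(assoc$snp_id %in% panel_snps)
    if (any(orphan)) {
      message(sprintf("excluding %d association rows with unknown SNP ids",
                      sum(orphan)))
      assoc <- assoc[!orphan, , drop = FALSE]
    }
  }
  flagged <- unique(unlist(method_flags))
  rows <- lapply(intersect(unique(assoc$snp_id), flagged), function(s) {
    traits <- unique(assoc$trait[assoc$snp_id == s])
    adaptive <- traits[trait_verdicts[traits]]
    if (length(adaptive) == 0) return(NULL)
    methods <- names(method_flags)[vapply(method_flags, function(f) s %in% f, TRUE)]
    data.frame(snp = s, methods = paste(methods, collapse = ","),
               n_methods = length(methods),
               sharing = if (length(methods) >= 2) "shared" else "unique",
               traits = paste(sort(traits), collapse = ","),
               adaptive_traits = paste(sort(adaptive), collapse = ","),
               pleiotropy = length(adaptive), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(adaptive_snp_report(assoc[0, , drop = FALSE],
                                                    trait_verdicts, method_flags))
  do.call(rbind, rows)
}

#' Correlation between per-trait outlier-associated and associated SNP counts
#'
#' Pearson correlation (with its two-sided p-value) across traits between
#' the number of outlier SNPs associated with the trait and the total
#' number of SNPs associated with it.
#'
#' @param counts data.frame with \code{n_outlier_assoc} and
#'   \code{n_assoc}, one row per trait (>= 5 traits).
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
outlier_assoc_correlation <- function(counts) {
  stopifnot(all(c("n_outlier_assoc", "n_assoc") %in% names(counts)))
  if (nrow(counts) < 5) stop("need >= 5 traits")
  if (sd(counts$n_outlier_assoc) == 0 || sd(counts$n_assoc) == 0)
    stop("zero variance in a count vector")
  ct <- cor.test(counts$n_outlier_assoc, counts$n_assoc, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(counts))
}
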