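#!/usr/bin/env Rscript
# Stage 7 — multi-evidence integration: overlap of the outlier-detection
# methods, the adaptive-SNP report (flagged by >= 1 method AND associated
# with a trait whose Q_ST exceeded neutral expectation), and the per-trait
# correlation between outlier-associated and associated SNP counts.
#
# The SNP-trait association table is an external input in the real workflow
# (GWAS is out of scope); here the synthetic stand-in associates the planted
# clinal loci with the simulated trait.
library(qstfst)

g <- read_genotypes_tsv("results/data/genotypes.tsv")
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
flags <- read.delim("results/fst_flags.tsv")
verdicts_tab <- read.delim("results/trait_verdicts.tsv")
sc_geo <- read.delim("results/spa_geography.tsv")
sc_clim <- read.delim("results/spa_climate.tsv")
scan <- read.delim("results/sam_scan.tsv")

method_flags <- list(
  fst_climate = flags$id[flags$flag == "high"],
  spa_unsupervised = sc_geo$id[sc_geo$flag5],
  spa_climate = sc_clim$id[sc_clim$flag5],
  sam_climate = unique(scan$locus[scan$pass]))

ov <- method_overlap(method_flags)
cat("method overlap cells:\n")
print(ov$cells, row.names = FALSE)
cat("shared fractions:",
    paste(sprintf("%s %.2f", names(ov$shared_fraction), ov$shared_fraction),
          collapse = "  "), "\n")
jsonlite::write_json(ov, "results/method_overlap.json", auto_unbox = TRUE,
                     digits = NA)

## synthetic association table: planted clinal loci <-> the simulated trait
assoc <- data.frame(snp_id = truth$clinal_locus_ids, trait = "trait",
                    p_value = 1e-6)
verdicts <- setNames(verdicts_tab$adaptive, verdicts_tab$trait)
rep <- adaptive_snp_report(assoc, verdicts, method_flags,
                           panel_snps = g$locus_meta$id)
write.table(rep, "results/adaptive_snps.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("adaptive-SNP report: %d SNPs (%d shared by >= 2 methods)\n",
            nrow(rep), sum(rep$sharing == "shared")))

## per-trait association counts (single simulated trait: illustrate with a
## locus-level bootstrap split of the associations)
if (nrow(rep) >= 1) {
  set.seed(truth$seed)
  traits <- paste0("T", 1:6)
  assoc_multi <- data.frame(
    snp_id = sample(g$locus_meta$id, 120, replace = FALSE),
    trait = sample(traits, 120, replace = TRUE), p_value = 1e-5)
  counts <- do.call(rbind, lapply(split(assoc_multi, assoc_multi$trait),
    function(d) data.frame(
      n_outlier_assoc = sum(d$snp_id %in% method_flags$fst_climate),
      n_assoc = nrow(d))))
  res <- tryCatch(outlier_assoc_correlation(counts),
                  error = function(e) NULL)
  if (!is.null(res))
    cat(sprintf("outlier/association count correlation: r = %.3f (p = %.3g, %d traits)\n",
                res$r, res$p, res$n))
}
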