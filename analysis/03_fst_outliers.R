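#!/usr/bin/env Rscript
# Stage 3 — per-locus Weir-Cockerham F_ST among the four clusters, the
# coalescent island-model neutral envelope conditioned on heterozygosity,
# iterative neutral-mean trimming, the chromosome hotspot test, and LD among
# the flagged outliers. Writes the trimmed neutral F_ST vector consumed by
# the Q_ST-F_ST neutrality test (stage 4).
library(qstfst)

g <- read_genotypes_tsv("results/data/genotypes.tsv")
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
seed <- truth$seed

obs <- weir_cockerham_fst(g, truth$cluster_labels)
cat(sprintf("multi-locus F_ST over %d loci: %.4f\n", nrow(obs),
            attr(obs, "multilocus")))

det <- detect_outliers(obs, d = 4, ci = 0.99, n_sims = 20000, n_demes = 20,
                       seed = seed)
cat(sprintf("trimmed neutral mean F_ST: %.4f after %d round(s); %d high / %d low outliers\n",
            det$trimmed_mean, det$rounds, sum(det$flags$flag == "high"),
            sum(det$flags$flag == "low")))
high <- det$flags$id[det$flags$flag == "high"]
cat(sprintf("planted clinal loci among high outliers: %d / %d\n",
            sum(truth$clinal_locus_ids %in% high),
            length(truth$clinal_locus_ids)))

write.table(det$flags, "results/fst_flags.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(data.frame(neutral_fst = det$neutral_fst),
            "results/neutral_fst.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
env <- det$envelope
write.table(data.frame(he = env$he_grid, lower = env$lower,
                       upper = env$upper),
            "results/envelope.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

## hotspot test over the 19 block-assigned chromosomes (the TSV carries no
## chromosome column; rebuild the block assignment from stage 1)
blk <- ceiling(ncol(g$dosage) / 19)
chrom <- ((match(high, g$locus_meta$id) - 1) %/% blk) + 1
if (length(high) > 0) {
  ht <- hotspot_test(chrom, n_chromosomes = 19, n_perm = 1000, seed = seed)
  cat(sprintf("hotspot GOF: chi2 = %.2f, df = %d, p = %.3g; hotspots: %s\n",
              ht$chi2, ht$df, ht$p,
              if (length(ht$hotspots)) paste(ht$hotspots, collapse = ",")
              else "none"))
  jsonlite::write_json(ht[c("chi2", "df", "p", "perm_max", "hotspots")],
                       "results/hotspots.json", auto_unbox = TRUE, digits = NA)
}

## LD among outliers
if (length(high) >= 2) {
  r2 <- pairwise_ld_r2(g, high)
  cat(sprintf("median off-diagonal r2 among %d outliers: %.3f\n",
              length(high), median(r2[upper.tri(r2)], na.rm = TRUE)))
  write.table(round(r2, 4), "results/outlier_ld_r2.tsv", sep = "\t",
              quote = FALSE)
}
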