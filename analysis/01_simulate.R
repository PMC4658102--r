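#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study: an island-model SNP panel over four
# weakly differentiated subpopulations (the role the climate clusters play),
# an isolation-by-distance landscape with coordinates, climate-of-origin
# variables with four planted zones, a handful of clinal loci, and clonally
# replicated phenotypes with known heritability and Q_ST.
#
# Everything downstream (02..07) reads the files written here, so the whole
# analysis is reproducible from one seed:  Rscript analysis/01_simulate.R [seed]
library(qstfst)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("results/data", showWarnings = FALSE)

cfg <- sim_config(n_pops = 4, n_per_pop = 100, n_loci = 5000,
                  target_fst = 0.01, n_clinal_loci = 10, cline_slope = 2,
                  h2_true = 0.5, qst_true = 0.2, n_ramets = 3, seed = seed)

## one panel carrying both structures of the study system: an
## isolation-by-distance background over the landscape, with a handful of
## loci overwritten by climate-driven logistic clines. The analysis
## "populations" are the spatial climate zones, so background
## differentiation among them is weak while the clinal loci diverge
## strongly — the configuration every downstream scan is built for.
ibd <- sim_ibd_genotypes(cfg)
clim <- sim_climate(ibd$coords, seed = seed)
mat_std <- scale(clim$climate$MAT)[, 1]
clin <- sim_clinal_loci(ibd$genotypes, mat_std, cfg)
g <- clin$genotypes
## chromosomes assigned in contiguous blocks of loci (19, as in poplar):
## the clinal block lands on one chromosome, a planted outlier hotspot
g$locus_meta$chrom <- as.character(((seq_len(ncol(g$dosage)) - 1) %/%
                                      ceiling(ncol(g$dosage) / 19)) + 1)

## phenotypes from the realized relationship matrix of the final panel,
## with among-cluster effects planted over the climate zones
G <- compute_grm(qc_filter_snps(g))
ph <- sim_phenotypes(G, clim$zone, cfg)

write_genotypes_tsv(g, "results/data/genotypes.tsv")
write_vcf_min(g[, 1:50], "results/data/genotypes_head.vcf")  # format sample
write.csv(ibd$coords, "results/data/coords.csv", row.names = FALSE)
write.csv(clim$climate, "results/data/climate.csv", row.names = FALSE)
write.csv(ph$phenotypes, "results/data/phenotypes.csv", row.names = FALSE)
truth <- list(cluster_labels = clim$zone,
              climate_zone = clim$zone,
              clinal_locus_ids = clin$clinal_locus_ids,
              sigma_p2 = ph$truth$sigma_p2, sigma_a2 = ph$truth$sigma_a2,
              sigma_e2 = ph$truth$sigma_e2, seed = seed)
jsonlite::write_json(truth, "results/data/truth.json", auto_unbox = TRUE)

cat(sprintf(
  "simulated %d genotypes x %d loci (%d clinal) over 4 climate zones,\n",
  nrow(g$dosage), ncol(g$dosage), length(clin$clinal_locus_ids)),
  sprintf("planted h2 = %.2f, Q_ST = %.2f, %d ramets/genotype -> results/data/\n",
          cfg$h2_true, cfg$qst_true, cfg$n_ramets))
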