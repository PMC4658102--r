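test_that("island generator hits its target F_ST and stays in the dosage codomain", {
  cfg <- sim_config(n_pops = 4, n_per_pop = 100, n_loci = 5000,
                    target_fst = 0.05, seed = 11)
  sim <- sim_island_genotypes(cfg)
  expect_true(all(sim$genotypes$dosage %in% c(0, 1, 2)))
  expect_equal(dim(sim$genotypes$dosage), c(400, 5000))
  f <- weir_cockerham_fst(sim$genotypes, sim$truth$cluster_labels)
  expect_gt(attr(f, "multilocus"), 0.04)
  expect_lt(attr(f, "multilocus"), 0.06)
})

test_that("target_fst = 0 yields a panmictic pool with F_ST near zero", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 100, n_loci = 5000,
                    target_fst = 0, seed = 7)
  sim <- sim_island_genotypes(cfg)
  expect_equal(sim$truth$deme_freq[1, ], sim$truth$deme_freq[2, ])
  f <- weir_cockerham_fst(sim$genotypes, sim$truth$cluster_labels)
  # theta is unbiased around 0 here; +/- 2 SE over 5000 loci is tiny
  expect_lt(abs(attr(f, "multilocus")), 0.005)
})

test_that("generators are seed-deterministic", {
  cfg <- sim_config(n_loci = 50, n_per_pop = 5, seed = 123)
  expect_identical(sim_island_genotypes(cfg)$genotypes$dosage,
                   sim_island_genotypes(cfg)$genotypes$dosage)
  expect_identical(sim_ibd_genotypes(cfg)$genotypes$dosage,
                   sim_ibd_genotypes(cfg)$genotypes$dosage)
  cfg2 <- sim_config(n_loci = 50, n_per_pop = 5, seed = 124)
  expect_false(identical(sim_island_genotypes(cfg)$genotypes$dosage,
                         sim_island_genotypes(cfg2)$genotypes$dosage))
})

test_that("IBD genotypes show positive short-range Moran autocorrelation that fades with distance", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 60, n_loci = 400,
                    target_fst = 0.1, dispersal_sigma = 150,
                    landscape_extent = 1000, seed = 5)
  sim <- sim_ibd_genotypes(cfg)
  pc1 <- prcomp(sim$genotypes$dosage, rank. = 1)$x[, 1]
  prof <- morans_lag_profile(pc1, sim$coords, lag_width = 200,
                             n_perm = 199, seed = 1)
  expect_gt(prof$I[1], 0)
  expect_lt(prof$p[1], 0.05)
  expect_gt(prof$I[1], prof$I[3])
})

test_that("infinite dispersal removes spatial structure", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 50, n_loci = 300,
                    target_fst = 0.05, dispersal_sigma = 1e9, seed = 5)
  sim <- sim_ibd_genotypes(cfg)
  pc1 <- prcomp(sim$genotypes$dosage, rank. = 1)$x[, 1]
  net <- build_network(sim$coords, "distance_band", lo = 0, hi = 200)
  mi <- morans_i(pc1, net, n_perm = 499, seed = 2)
  expect_gt(mi$p, 0.05)
})

test_that("clinal overwrite touches only the selected loci and respects slope = 0", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 50, n_loci = 100,
                    n_clinal_loci = 5, cline_slope = 3, seed = 9)
  sim <- sim_island_genotypes(cfg)
  z <- rnorm(100)
  out <- sim_clinal_loci(sim$genotypes, z, cfg)
  expect_length(out$clinal_locus_ids, 5)
  untouched <- setdiff(colnames(sim$genotypes$dosage), out$clinal_locus_ids)
  expect_identical(out$genotypes$dosage[, untouched],
                   sim$genotypes$dosage[, untouched])

  cfg0 <- sim_config(n_pops = 2, n_per_pop = 50, n_loci = 100,
                     n_clinal_loci = 0, seed = 9)
  out0 <- sim_clinal_loci(sim$genotypes, z, cfg0)
  expect_identical(out0$genotypes$dosage, sim$genotypes$dosage)

  cfgf <- sim_config(n_pops = 2, n_per_pop = 50, n_loci = 100,
                     n_clinal_loci = 5, cline_slope = 0, seed = 9)
  expect_warning(outf <- sim_clinal_loci(sim$genotypes, z, cfgf),
                 "indistinguishable")
  # spatially constant expected frequency: all rows of the planted
  # frequency matrix identical
  expect_equal(apply(outf$expected_freq, 2, sd), rep(0, 5))
})

test_that("simulated climate has correlated MAT/NFFD and recoverable zones", {
  cfg <- sim_config(seed = 21)
  sim <- sim_ibd_genotypes(sim_config(n_pops = 4, n_per_pop = 50,
                                      n_loci = 10, seed = 21))
  clim <- sim_climate(sim$coords, seed = 21)
  expect_true(all(clim$climate$MAP >= 0))
  expect_true(all(clim$climate$NFFD >= 0 & clim$climate$NFFD <= 366))
  expect_gt(cor(clim$climate$MAT, clim$climate$NFFD), 0)
  cl <- kmedoids_ch(clim$climate[, c("MAT", "NFFD", "MAP")], k_range = 2:6,
                    seed = 1)
  expect_equal(cl$K, 4)
  expect_gte(mclust::adjustedRandIndex(cl$labels, clim$zone), 0.9)
})

test_that("phenotype generator plants the requested variance components", {
  cfg <- sim_config(n_pops = 4, n_per_pop = 50, n_loci = 100,
                    h2_true = 0.6, qst_true = 0.25, n_ramets = 3, seed = 31)
  n <- 200
  G <- diag(n); rownames(G) <- sprintf("g%03d", 1:n)
  clusters <- rep(1:4, each = 50)
  ph <- sim_phenotypes(G, clusters, cfg)
  tr <- ph$truth
  expect_equal(tr$sigma_a2, 0.6)
  expect_equal(tr$sigma_e2, 0.4)
  expect_equal(tr$sigma_p2, 2 * 0.6 * 0.25 / 0.75)
  # cluster effects carry exactly sigma2_p (d-1 denominator)
  expect_equal(var(tr$cluster_effects), tr$sigma_p2)
  expect_equal(nrow(ph$phenotypes), n * 3)
  # ramets of a genotype share genotype and cluster effects: within-clone
  # variance is residual only
  w <- tapply(ph$phenotypes$trait, ph$phenotypes$genotype_id, var)
  expect_equal(mean(w), tr$sigma_e2, tolerance = 0.15)
  # qst_true = 0 plants no divergence
  cfg0 <- sim_config(n_pops = 4, n_per_pop = 50, qst_true = 0, seed = 31)
  ph0 <- sim_phenotypes(G, clusters, cfg0)
  expect_equal(unname(ph0$truth$cluster_effects), rep(0, 4))
})
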