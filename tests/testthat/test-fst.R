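test_that("Weir-Cockerham theta matches the textbook oracle to 1e-12", {
  # two pops of 10 diploids, alternate-allele counts 6/20 vs 14/20, HWE
  # genotype counts: p = 0.3 -> (4.9, 4.2, 0.9) rounded to a realizable
  # configuration; build exact HWE-like integer panels instead
  make_pop <- function(n_aa, n_ab, n_bb) rep(c(0, 1, 2), c(n_aa, n_ab, n_bb))
  dos <- cbind(c(make_pop(5, 4, 1), make_pop(2, 6, 2)))
  pops <- rep(1:2, each = 10)
  ft <- weir_cockerham_fst(cbind(dos, dos), pops)   # two identical loci
  p_i <- c(6 / 20, 10 / 20)
  h_i <- c(4 / 10, 6 / 10)
  o <- oracle_wc_theta(c(10, 10), p_i, h_i)
  expect_equal(ft$fst[1], o$theta, tolerance = 1e-12)
  expect_equal(ft$a[1], o$a, tolerance = 1e-12)
  expect_equal(ft$he[1], 2 * 0.4 * 0.6, tolerance = 1e-12)
})

test_that("theta behaves at the no-differentiation and fixation extremes", {
  # identical allele counts in both pops
  pop <- rep(c(0, 1, 2), c(5, 6, 9))
  dos <- cbind(c(pop, pop))
  ft <- weir_cockerham_fst(dos, rep(1:2, each = 20))
  expect_lte(ft$fst[1], 0)
  expect_lt(abs(ft$fst[1]), 0.06)
  # fixed difference
  dos2 <- cbind(rep(c(0, 2), each = 50))
  ft2 <- weir_cockerham_fst(dos2, rep(1:2, each = 50))
  expect_gt(ft2$fst[1], 0.95)
  # monomorphic across pops -> NA
  ft3 <- weir_cockerham_fst(cbind(rep(2, 40), rep(c(0, 1), 20)),
                            rep(1:2, each = 20))
  expect_true(is.na(ft3$fst[1]))
  expect_false(is.na(ft3$fst[2]))
})

test_that("multi-locus theta of an island panel tracks the generator target", {
  cfg <- sim_config(n_pops = 4, n_per_pop = 50, n_loci = 5000,
                    target_fst = 0.1, seed = 19)
  sim <- sim_island_genotypes(cfg)
  ml <- attr(weir_cockerham_fst(sim$genotypes, sim$truth$cluster_labels),
             "multilocus")
  expect_lt(abs(ml - 0.1) / 0.1, 0.2)
})

test_that("island-model null calibrates its migration rate and is reproducible", {
  null <- island_null_simulate(0.0078, d = 4, n_demes = 20, n_sims = 4000,
                               seed = 23, pilot = 1500)
  expect_lt(abs(null$achieved_mean_fst - 0.0078) / 0.0078, 0.25)
  expect_true(all(null$pairs$he >= 0.02 & null$pairs$he <= 0.5))
  null2 <- island_null_simulate(0.0078, d = 4, n_demes = 20, n_sims = 4000,
                                seed = 23, pilot = 1500)
  expect_identical(null$pairs, null2$pairs)
})

test_that("envelope quantiles are calibrated and non-crossing", {
  null <- island_null_simulate(0.01, d = 4, n_demes = 20, n_sims = 12000,
                               seed = 29, pilot = 1500)
  env <- conditional_envelope(null$pairs, ci = 0.99)
  expect_true(all(env$lower < env$upper))
  # fresh neutral test set from the same process: ~1% outside
  test_set <- island_null_simulate(0.01, d = 4, n_demes = 20, n_sims = 10000,
                                   seed = 31, M = null$M_used)
  b <- envelope_bounds(env, test_set$pairs$he)
  frac_out <- mean(test_set$pairs$fst > b$upper | test_set$pairs$fst < b$lower)
  # binned empirical quantiles carry estimation noise that inflates the
  # nominal 1% exceedance slightly out of sample; see the methods vignette
  expect_gt(frac_out, 0.005)
  expect_lt(frac_out, 0.02)
  # in sample the envelope reproduces its nominal level by construction
  b_in <- envelope_bounds(env, null$pairs$he)
  frac_in <- mean(null$pairs$fst > b_in$upper | null$pairs$fst < b_in$lower)
  expect_lt(abs(frac_in - 0.01), 0.005)
  expect_error(conditional_envelope(null$pairs, ci = 0.3), "ci")
  expect_error(conditional_envelope(null$pairs[1:500, ], ci = 0.99), "10,000")
})

test_that("outlier trimming finds planted outliers and is order-invariant", {
  cfg <- sim_config(n_pops = 4, n_per_pop = 25, n_loci = 98,
                    target_fst = 0.01, seed = 37)
  sim <- sim_island_genotypes(cfg)
  # plant 2 strongly differentiated loci
  strong <- sim_island_genotypes(sim_config(n_pops = 4, n_per_pop = 25,
                                            n_loci = 2, target_fst = 0.5,
                                            seed = 38))
  dos <- cbind(sim$genotypes$dosage, strong$genotypes$dosage)
  colnames(dos) <- sprintf("L%03d", 1:100)
  obs <- weir_cockerham_fst(dos, sim$truth$cluster_labels)
  res <- suppressWarnings(
    detect_outliers(obs, d = 4, n_sims = 10000, n_demes = 20, seed = 39))
  expect_true(all(c("L099", "L100") %in% res$flags$id[res$flags$flag == "high"]))
  expect_lt(res$trimmed_mean, multilocus_fst(obs))
  expect_lt(abs(res$trimmed_mean - 0.01), 0.01)
  # order invariance
  perm <- sample(100)
  obs_p <- weir_cockerham_fst(dos[, perm], sim$truth$cluster_labels)
  res_p <- suppressWarnings(
    detect_outliers(obs_p, d = 4, n_sims = 10000, n_demes = 20, seed = 39))
  expect_setequal(res_p$flags$id[res_p$flags$flag == "high"],
                  res$flags$id[res$flags$flag == "high"])
})

test_that("hotspot GOF arithmetic matches the direct computation", {
  # all 118 outliers on one of 19 chromosomes
  ht <- hotspot_test(rep(7, 118), n_chromosomes = 19, n_perm = 200, seed = 1)
  e <- 118 / 19
  expect_equal(ht$chi2, (118 - e)^2 / e + 18 * e, tolerance = 1e-10)
  expect_equal(ht$df, 18)
  expect_gt(ht$chi2, 1000)
  expect_true(7 %in% ht$hotspots)
  # perfectly uniform counts
  ht2 <- hotspot_test(rep(1:19, each = 6), 19, n_perm = 200, seed = 2)
  expect_equal(ht2$chi2, 0)
  expect_length(ht2$hotspots, 0)
  expect_error(hotspot_test(integer(0), 19), "no outlier")
})

test_that("composite LD r2 has the right fixed points and recovers correlation", {
  g <- toy_panel(n = 200, m = 4, seed = 61)
  g$dosage[, 2] <- g$dosage[, 1]          # duplicated locus
  r2 <- pairwise_ld_r2(g)
  expect_equal(diag(r2), rep(1, 4), ignore_attr = TRUE)
  expect_equal(r2[1, 2], 1)
  # construct dosage correlation ~ 0.5 -> r2 ~ 0.25
  set.seed(62)
  x <- rbinom(4000, 2, 0.5)
  y <- ifelse(runif(4000) < 0.5, x, rbinom(4000, 2, 0.5))
  r2b <- pairwise_ld_r2(genotype_matrix(cbind(a = x, b = y)))
  expect_equal(r2b[1, 2], cor(x, y)^2, tolerance = 1e-12)
  expect_lt(abs(r2b[1, 2] - 0.25), 0.08)
  # monomorphic locus: NA row/column
  g2 <- genotype_matrix(cbind(x = c(0, 1, 2, 1), y = rep(2, 4)))
  r2c <- pairwise_ld_r2(g2)
  expect_true(is.na(r2c[1, 2]) && is.na(r2c[2, 2]))
})
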