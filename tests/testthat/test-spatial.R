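test_that("projection is meridian-faithful and dedup is seed-deterministic", {
  coords <- data.frame(id = c("a", "b"), lat = c(50, 51), lon = c(-120, -120))
  pl <- prepare_locations(coords, seed = 1)
  d <- sqrt(diff(pl$projected$x_km)^2 + diff(pl$projected$y_km)^2)
  expect_lt(abs(d - 111.2) / 111.2, 0.01)

  # 3 individuals at one location: exactly one representative, stable per seed
  coords3 <- data.frame(id = c("a", "b", "c", "d"),
                        lat = c(50, 50, 50, 51), lon = c(-120, -120, -120, -119))
  p1 <- prepare_locations(coords3, seed = 5)
  p2 <- prepare_locations(coords3, seed = 5)
  expect_equal(nrow(p1$representatives), 2)
  expect_identical(p1$representatives$id, p2$representatives$id)
  # idempotent on deduplicated input
  p3 <- prepare_locations(p1$representatives[, c("id", "lat", "lon")], seed = 5)
  expect_identical(p3$representatives$id, p1$representatives$id)
  # unique locations map 1:1 to representatives
  set.seed(71)
  many <- data.frame(id = sprintf("i%03d", 1:140),
                     lat = runif(140, 44, 60), lon = runif(140, -130, -120))
  expect_equal(nrow(prepare_locations(many, seed = 1)$representatives), 140)
  # missing coordinates are excluded with a log line
  many$lat[3] <- NA
  expect_message(pm <- prepare_locations(many, seed = 1), "excluding 1")
  expect_identical(pm$dropped, "i003")
})

test_that("knn networks symmetrize by union; distance bands follow (lo, hi]", {
  coords <- data.frame(id = 1:3, x_km = c(0, 10, 100), y_km = 0)
  net <- build_network(coords, "knn", k = 1)
  expect_equal(net$A[2, ], c(1, 0, 1), ignore_attr = TRUE)  # middle node
  expect_equal(net$A, t(net$A))
  expect_equal(diag(net$A), rep(0L, 3), ignore_attr = TRUE)

  c2 <- data.frame(id = 1:2, x_km = c(0, 150), y_km = 0)
  expect_equal(build_network(c2, "distance_band", lo = 0, hi = 200)$A[1, 2], 1L)
  c3 <- data.frame(id = 1:2, x_km = c(0, 250), y_km = 0)
  expect_equal(build_network(c3, "distance_band", lo = 0, hi = 200)$A[1, 2], 0L)
  # row-standardized weights sum to one (or zero when isolated)
  w <- build_network(c3, "distance_band", lo = 0, hi = 200)
  expect_equal(rowSums(w$W), c(0, 0), ignore_attr = TRUE)
  expect_length(w$isolated, 2)
  # coincident nodes are refused for knn
  cc <- data.frame(id = 1:12, x_km = c(0, 0, 1:10), y_km = 0)
  expect_error(build_network(cc, "knn", k = 2), "coincident")
})

test_that("Moran's I equals the double-loop evaluation and its permutation null", {
  # perfect linear cline on a path graph
  n <- 30
  coords <- data.frame(id = 1:n, x_km = seq(0, 290, by = 10), y_km = 0)
  net <- build_network(coords, "distance_band", lo = 0, hi = 10.5)
  x <- seq_len(n)
  mi <- morans_i(x, net, n_perm = 499, seed = 3)
  expect_equal(mi$I, oracle_moran(x, net$A), tolerance = 1e-12)
  expect_gt(mi$I, 0.9)
  expect_lt(mi$p, 0.01)
  # permutation mean approximates -1/(n-1)
  expect_lt(abs(mi$perm_mean - (-1 / (n - 1))), 3 * mi$perm_sd / sqrt(499) * 5)
  # alternating signal on the path: negative autocorrelation
  alt <- rep(c(1, -1), n / 2)
  expect_lt(morans_i(alt, net, n_perm = 99, seed = 4)$I, 0)
  expect_error(morans_i(rep(1, n), net), "zero variance")
  # random vectors: oracle equality holds for arbitrary input
  set.seed(5)
  for (i in 1:3) {
    x <- rnorm(n)
    expect_equal(morans_i(x, net, n_perm = 99, seed = i)$I,
                 oracle_moran(x, net$A), tolerance = 1e-12)
  }
})

test_that("lag profile uses 200 km bands and skips empty ones", {
  set.seed(6)
  coords <- data.frame(id = 1:40, x_km = c(runif(20, 0, 100), runif(20, 500, 600)),
                       y_km = runif(40, 0, 50))
  x <- rnorm(40)
  expect_message(prof <- morans_lag_profile(x, coords, lag_width = 200,
                                            n_perm = 99, seed = 1),
                 "skipped")
  expect_true(all(prof$lag_hi - prof$lag_lo == 200))
  expect_true(all(prof$n_edges > 0))
})

test_that("sPCA eigenvalues satisfy the trace and var x Moran identities", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 40, n_loci = 120,
                    target_fst = 0.08, dispersal_sigma = 200, seed = 73)
  sim <- sim_ibd_genotypes(cfg)
  net <- build_network(sim$coords, "knn", k = 10)
  sp <- spca(sim$genotypes, net, n_perm = 99, seed = 1)
  # trace identity
  X <- scale(sim$genotypes$dosage, center = TRUE, scale = FALSE)
  H <- (net$W + t(net$W)) / (2 * nrow(X))
  expect_equal(sum(sp$eigenvalues), sum(diag(t(X) %*% H %*% X)),
               tolerance = 1e-8)
  # eigenvalue = var(score) x Moran's I(score) (row-standardized, S0 = n)
  s1 <- sp$scores[, 1]
  I1 <- (nrow(X) / sum(net$W)) *
    drop(crossprod(s1 - mean(s1), net$W %*% (s1 - mean(s1)))) /
    sum((s1 - mean(s1))^2)
  expect_equal(sp$eigenvalues[1], var(s1) * (length(s1) - 1) / length(s1) * I1 *
                 sum(net$W) / nrow(X), tolerance = 1e-6)
  expect_error(spca(sim$genotypes, net, n_perm = 50), "99")
})

test_that("sPCA separates IBD from panmixia", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 50, n_loci = 300,
                    target_fst = 0.1, dispersal_sigma = 150, seed = 79)
  sim <- sim_ibd_genotypes(cfg)
  net <- build_network(sim$coords, "knn", k = 10)
  sp <- spca(sim$genotypes, net, n_perm = 99, seed = 2)
  expect_gt(sp$eigenvalues[1], 0)
  expect_lte(sp$global_p, 0.05)
  expect_gt(sp$local_p, 0.05)
  # spatially shuffled genotypes lose significance
  shuf <- sim$genotypes
  set.seed(80)
  shuf$dosage <- shuf$dosage[sample(nrow(shuf$dosage)), ]
  sp0 <- spca(genotype_matrix(shuf$dosage), net, n_perm = 99, seed = 3)
  expect_gte(sp0$global_p, 0.05)
})

test_that("SPA scores are allele-label invariant and recover generating slopes", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 150, n_loci = 60,
                    n_clinal_loci = 20, cline_slope = 2, seed = 83)
  sim <- sim_ibd_genotypes(cfg)
  z <- sim$coords$y_km / 1000   # northing in Mm: slope is per 1000 km
  out <- sim_clinal_loci(sim$genotypes, z, cfg)
  sc <- spa_cline_scores(out$genotypes, cbind(northing = z))
  cl <- sc$id %in% out$clinal_locus_ids
  # planted clines score above the neutral background
  expect_gt(median(sc$score[cl]), quantile(sc$score[!cl], 0.95))
  # original-units slope recovery within 25%
  expect_lt(abs(median(abs(sc$slope_northing[cl])) - 2) / 2, 0.25)
  # allele relabeling flips the slope sign, not the score
  flip <- out$genotypes
  flip$dosage <- 2 - flip$dosage
  sc2 <- spa_cline_scores(genotype_matrix(flip$dosage), cbind(northing = z))
  expect_equal(sc2$score, sc$score, tolerance = 1e-6)
  expect_equal(sc2$slope_northing, -sc$slope_northing, tolerance = 1e-6)
  # flag rates follow the quantile definition
  expect_equal(mean(sc$flag5), 0.05, tolerance = 0.05)
})
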