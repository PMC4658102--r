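test_that("K-medoids with CH selection recovers separated clusters", {
  set.seed(1)
  centers <- matrix(c(0, 0, 0, 8, 8, 0, 4, -8), 4, 2, byrow = TRUE)[1:3, ]
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(80, sd = 0.4), 40, 2), 2, centers[k, ], `+`)))
  df <- data.frame(MAT = X[, 1], NFFD = X[, 2])
  cl <- kmedoids_ch(df, k_range = 2:6, seed = 2)
  expect_equal(cl$K, 3)
  truth <- rep(1:3, each = 40)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  expect_equal(which.max(cl$ch_by_k), match("3", names(cl$ch_by_k)),
               ignore_attr = TRUE)

  # invariant to affine rescaling of a variable (standardization)
  df2 <- transform(df, NFFD = 1000 * NFFD + 7)
  cl2 <- kmedoids_ch(df2, k_range = 2:6, seed = 2)
  expect_equal(cl2$labels, cl$labels)

  # duplicating every point keeps the same medoid positions
  cl3 <- kmedoids_ch(rbind(df, df), k_range = 3, seed = 2)
  med1 <- df[cl$medoids, ]
  med3 <- rbind(df, df)[cl3$medoids, ]
  expect_equal(sort(med3$MAT), sort(med1$MAT), tolerance = 1e-12)
  expect_error(kmedoids_ch(df, k_range = integer(0)), "empty")
  expect_error(kmedoids_ch(df, k_range = c(2, 90)), "n/5")
})

test_that("Bonferroni bookkeeping reproduces the 726-model threshold", {
  # 242 alleles x 3 variables at alpha = 0.05
  expect_equal(0.05 / (242 * 3), 6.887052e-5, tolerance = 1e-6)
  set.seed(3)
  dos <- matrix(rbinom(40 * 242, 2, 0.4), 40, 242)
  # guarantee polymorphism
  dos[1, ] <- 0; dos[2, ] <- 2
  env <- data.frame(MAT = rnorm(40), NFFD = rnorm(40), MAP = rnorm(40))
  res <- sam_scan(genotype_matrix(dos), env, alpha = 0.05, mode = "individual")
  expect_equal(attr(res, "n_models"), 726)
  expect_equal(nrow(res), 726)
  expect_equal(attr(res, "threshold"), 0.05 / 726, tolerance = 1e-12)
})

test_that("SAM LR statistic matches an independent likelihood evaluation", {
  set.seed(4)
  n <- 120
  z <- rnorm(n)
  pr <- plogis(-0.3 + 0.8 * z)
  dos <- cbind(rbinom(n, 2, pr))
  env <- data.frame(v = z)
  res <- sam_scan(genotype_matrix(dos), env, mode = "individual")
  # oracle: direct binomial log-likelihoods at the fitted and null optima
  yp <- dos[, 1] / 2; w <- rep(2, n)
  fit <- glm(yp ~ z, weights = w, family = binomial())
  ll_full <- oracle_logit_ll(coef(fit), cbind(1, z), yp, w)
  ll_null <- oracle_logit_ll(qlogis(mean(yp)), matrix(1, n, 1), yp, w)
  expect_equal(res$lr_stat, 2 * (ll_full - ll_null), tolerance = 1e-8)
  # the three tests agree asymptotically on a strong signal
  expect_lt(res$lr_p, 1e-4)
  expect_lt(res$wald_p, 1e-3)
  expect_lt(res$score_p, 1e-4)
})

test_that("a strong environmental dependence passes all three tests", {
  set.seed(5)
  n <- 400
  mat <- rnorm(n)
  dos <- cbind(rbinom(n, 2, plogis(3 * mat)),
               rbinom(n, 2, 0.5))
  env <- data.frame(MAT = mat)
  res <- sam_scan(genotype_matrix(dos), env, alpha = 0.05, mode = "individual")
  expect_true(res$pass[res$locus == "snp_00001"])
  expect_false(res$pass[res$locus == "snp_00002"])
})

test_that("permuted environments keep the family-wise error controlled", {
  set.seed(6)
  n <- 100; m <- 40
  dos <- matrix(rbinom(n * m, 2, 0.4), n, m)
  dos[1, ] <- 0; dos[2, ] <- 2
  g <- genotype_matrix(dos)
  fwer_hits <- 0
  for (s in 1:40) {
    set.seed(1000 + s)
    env <- data.frame(v1 = rnorm(n), v2 = rnorm(n))
    res <- sam_scan(g, env, alpha = 0.05, mode = "individual")
    if (any(res$pass)) fwer_hits <- fwer_hits + 1
  }
  # binomial(40, 0.05) upper tail: > 7 hits would be wildly miscalibrated
  expect_lte(fwer_hits, 7)
})

test_that("cluster-mean mode assigns each individual its cluster average", {
  set.seed(7)
  n <- 60
  clusters <- rep(1:3, each = 20)
  env <- data.frame(MAT = rnorm(n))
  dos <- cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.4))
  dos[1, ] <- 0; dos[2, ] <- 2
  g <- genotype_matrix(dos)
  res_cm <- sam_scan(g, env, mode = "cluster_mean", clusters = clusters)
  env_cm <- data.frame(MAT = ave(env$MAT, clusters))
  res_ind <- sam_scan(g, env_cm, mode = "individual")
  expect_equal(res_cm$lr_stat, res_ind$lr_stat, tolerance = 1e-12)
  expect_error(sam_scan(g, env, mode = "cluster_mean"), "cluster labels")
})

test_that("cluster frequency regressions hit their algebraic fixed points", {
  # frequencies exactly linear in arcsine scale across 4 clusters
  tvals <- c(0.3, 0.5, 0.7, 0.9)
  f <- sin(tvals)^2
  # build dosage whose cluster frequencies are exactly f
  make_cluster <- function(freq, n = 10) {
    cnt <- round(freq * 2 * n)
    rep(c(2, 1, 0), c(cnt %/% 2, cnt %% 2, n - cnt %/% 2 - cnt %% 2))
  }
  dos <- cbind(unlist(lapply(f, make_cluster)))
  clusters <- rep(1:4, each = 10)
  realized_f <- tapply(dos[, 1], clusters, function(x) mean(x) / 2)
  climate_means <- data.frame(MAT = asin(sqrt(realized_f)))  # exact linearity
  out <- cluster_freq_regression(genotype_matrix(dos), clusters, climate_means)
  expect_equal(out$r2, 1, tolerance = 1e-9)
  expect_equal(out$slope, 1, tolerance = 1e-9)

  # constant frequencies: R2 = 0, slope = 0
  dos2 <- cbind(rep(make_cluster(0.5), 4))
  out2 <- cluster_freq_regression(genotype_matrix(dos2), clusters,
                                  data.frame(MAT = c(1, 2, 3, 4)))
  expect_equal(out2$r2, 0)
  expect_equal(out2$slope, 0)

  # arcsine transform is monotone; boundary frequencies are flagged
  expect_true(all(diff(asin(sqrt(seq(0, 1, 0.1)))) > 0))
  dos3 <- cbind(c(rep(0, 10), make_cluster(0.4), make_cluster(0.6), rep(2, 10)))
  out3 <- cluster_freq_regression(genotype_matrix(dos3), clusters,
                                  data.frame(MAT = 1:4))
  expect_true(all(out3$boundary))
  # relabeling clusters leaves R2 unchanged
  relab <- c(3, 1, 4, 2)[clusters]
  cm <- data.frame(MAT = (1:4)[order(c(3, 1, 4, 2))])
  out4 <- cluster_freq_regression(genotype_matrix(dos3), relab,
                                  data.frame(MAT = c(2, 4, 1, 3)))
  expect_equal(out4$r2, out3$r2, tolerance = 1e-9)
})
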