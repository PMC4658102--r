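#' Climate-envelope clustering by K-medoids with Calinski-Harabasz selection
#'
#' Standardizes the climate variables (zero mean, unit variance), runs PAM
#' (build + swap) on Euclidean distances for each candidate K, computes a
#' PAM-flavored Calinski-Harabasz index using the medoids as cluster
#' centers, and returns the partition maximizing it. Standardization makes
#' the result invariant to affine rescaling of any variable.
#'
#' @param climate data.frame of climate variables (non-numeric and id
#'   columns dropped); typically MAT, NFFD, MAP.
#' @param k_range candidate numbers of clusters (each must satisfy
#'   2 <= k <= n/5).
#' @param seed integer seed (tie-breaking).
#' @return a \code{climate_clusters}: labels, medoid indices, K,
#'   ch_by_k.
#' @export
kmedoids_ch <- function(climate, k_range = 2:8, seed = 1L) {
  num <- climate[, vapply(climate, is.numeric, TRUE), drop = FALSE]
  Xs <- scale(as.matrix(num))
  n <- nrow(Xs)
  if (length(k_range) == 0) stop("empty k_range")
  if (any(k_range < 2 | k_range > n / 5))
    stop("every k must satisfy 2 <= k <= n/5")
  set.seed(seed)
  ch <- setNames(numeric(length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  gmean <- colMeans(Xs)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- cluster::pam(Xs, k = k, metric = "euclidean")
    med <- Xs[fit$id.med, , drop = FALSE]
    withinss <- sum((Xs - med[fit$clustering, , drop = FALSE])^2)
    nk <- tabulate(fit$clustering, k)
    betweenss <- sum(nk * rowSums(sweep(med, 2, gmean)^2))
    ch[i] <- (betweenss / (k - 1)) / (withinss / (n - k))
    fits[[i]] <- fit
  }
  best <- which.max(ch)
  fit <- fits[[best]]
  structure(list(labels = fit$clustering, medoids = fit$id.med,
                 K = k_range[best], ch_by_k = ch),
            class = "climate_clusters")
}

#' @export
print.climate_clusters <- function(x, ...) {
  cat(sprintf("K-medoids clustering: K = %d (CH %.2f), sizes %s\n", x$K,
              x$ch_by_k[as.character(x$K)],
              paste(tabulate(x$labels, x$K), collapse = "/")))
  invisible(x)
}

## Score (Lagrange multiplier) test of the slope in a univariate logistic
## regression of allele presence, evaluated under the intercept-only null.
logistic_score_test <- function(y_prop, w, v) {
  mu0 <- sum(w * y_prop) / sum(w)
  U <- sum(w * (y_prop - mu0) * v)
  q <- mu0 * (1 - mu0)
  i11 <- sum(w * q); i1v <- sum(w * q * v); ivv <- sum(w * q * v^2)
  Veff <- ivv - i1v^2 / i11
  stat <- U^2 / Veff
  c(stat = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

#' Allele-frequency / environment association scan
#'
#' Univariate logistic regressions of allele presence on each environmental
#' variable (each diploid contributing two allele draws), with three test
#' statistics per model: the likelihood-ratio test against the
#' intercept-only model, the Wald test on the slope, and the score
#' (Lagrange-multiplier) test. A model passes only when all three p-values
#' fall below the family-wise Bonferroni threshold alpha / (n_alleles x
#' n_variables). By default each individual carries its subpopulation's
#' mean environment (the climate-cluster usage); per-individual values are
#' available via \code{mode = "individual"}. Separated fits are flagged,
#' their Wald p set missing, and the pass decided by the remaining two
#' tests.
#'
#' @param g a [genotype_matrix()]; one tested allele per polymorphic locus.
#' @param env data.frame of environmental variables, one row per
#'   individual.
#' @param alpha family-wise error level (default 0.05).
#' @param mode "cluster_mean" (default) or "individual".
#' @param clusters cluster labels per individual (required for
#'   cluster_mean mode).
#' @return a \code{sam_result} data.frame, one row per allele x variable:
#'   slope, lr/wald/score statistics and p-values, separation and pass
#'   flags; attributes \code{threshold} and \code{n_models}.
#' @export
sam_scan <- function(g, env, alpha = 0.05,
                     mode = c("cluster_mean", "individual"),
                     clusters = NULL) {
  mode <- match.arg(mode)
  dos <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  env <- as.data.frame(env)
  env <- env[, vapply(env, is.numeric, TRUE), drop = FALSE]
  stopifnot(nrow(env) == nrow(dos))
  if (mode == "cluster_mean") {
    if (is.null(clusters)) stop("cluster_mean mode needs cluster labels")
    for (v in names(env))
      env[[v]] <- ave(env[[v]], clusters)
  }
  if (any(vapply(env, sd, 0) == 0)) stop("constant environmental variable")

  p <- colMeans(dos, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  loci <- colnames(dos)[poly]
  n_alleles <- length(loci)
  n_models <- n_alleles * ncol(env)
  threshold <- alpha / n_models

  rows <- vector("list", n_models)
  idx <- 0L
  for (j in which(poly)) {
    y <- dos[, j]
    okr <- !is.na(y)
    yp <- y[okr] / 2
    w <- rep(2, sum(okr))
    ll_null <- {
      mu0 <- mean(yp)
      sum(w * (yp * log(mu0) + (1 - yp) * log(1 - mu0)))
    }
    for (v in names(env)) {
      z <- env[[v]][okr]
      fit <- suppressWarnings(glm(yp ~ z, weights = w, family = binomial()))
      b <- coef(fit)[["z"]]
      se <- sqrt(diag(vcov(fit)))[["z"]]
      mu <- fitted(fit)
      ll_full <- sum(w * (yp * log(mu) + (1 - yp) * log(1 - mu)))
      lr <- max(2 * (ll_full - ll_null), 0)
      separation <- !fit$converged || abs(b) > 1e3 || se > 1e3
      wald <- if (separation) NA_real_ else (b / se)^2
      sc <- logistic_score_test(yp, w, z)
      lr_p <- pchisq(lr, 1, lower.tail = FALSE)
      wald_p <- if (is.na(wald)) NA_real_ else pchisq(wald, 1, lower.tail = FALSE)
      pass <- if (separation) (lr_p < threshold && sc[["p"]] < threshold)
              else (lr_p < threshold && wald_p < threshold && sc[["p"]] < threshold)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        locus = colnames(dos)[j], variable = v, slope = b,
        lr_stat = lr, lr_p = lr_p, wald_stat = wald, wald_p = wald_p,
        score_stat = sc[["stat"]], score_p = sc[["p"]],
        separation = separation, pass = pass, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  attr(out, "n_models") <- n_models
  attr(out, "n_alleles") <- n_alleles
  class(out) <- c("sam_result", "data.frame")
  out
}

#' Cluster-level allele-frequency / climate regressions
#'
#' For each locus, computes the allele frequency per cluster, applies the
#' variance-stabilizing arcsine square-root transform (defined at 0 and 1,
#' flagged as boundary there), and regresses the transformed frequencies on
#' each cluster-mean climate variable by ordinary least squares.
#'
#' @param g a [genotype_matrix()].
#' @param clusters cluster labels per individual (>= 3 clusters).
#' @param climate_means data.frame of cluster-level climate means, rows in
#'   sorted cluster-label order.
#' @return data.frame per locus x variable: slope, r2, p, boundary flag.
#' @export
cluster_freq_regression <- function(g, clusters, climate_means) {
  dos <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  cl <- factor(clusters)
  k <- nlevels(cl)
  if (k < 3) stop("need >= 3 clusters for a frequency regression")
  climate_means <- as.data.frame(climate_means)
  stopifnot(nrow(climate_means) == k)
  ok <- !is.na(dos)
  fk <- rowsum(ifelse(ok, dos, 0), cl) / (2 * rowsum(ok + 0, cl))  # k x m freqs
  tk <- asin(sqrt(fk))
  rows <- list()
  for (j in seq_len(ncol(dos))) {
    boundary <- any(fk[, j] %in% c(0, 1))
    for (v in names(climate_means)) {
      fit <- lm(tk[, j] ~ climate_means[[v]])
      sm <- suppressWarnings(summary(fit))
      slope <- coef(fit)[2]
      pv <- if (is.na(slope) || sm$sigma == 0) NA_real_
            else coef(sm)[2, 4]
      if (sd(tk[, j]) == 0) { slope <- 0; pv <- 1 }
      rows[[length(rows) + 1]] <- data.frame(
        locus = colnames(dos)[j], variable = v,
        slope = ifelse(is.na(slope), 0, slope),
        r2 = ifelse(is.na(sm$r.squared), 0, sm$r.squared),
        p = pv, boundary = boundary, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
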