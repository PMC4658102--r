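#' Simulate climate-of-origin variables over a sampled landscape
#'
#' Plants K latent climate zones on the landscape (spatial Voronoi zones from
#' a k-means partition of the coordinates) and draws, per individual, mean
#' annual temperature (MAT, degrees C), number of frost-free days (NFFD) and
#' mean annual precipitation (MAP, mm). NFFD is generated as an affine
#' function of realized MAT plus noise, so the two are positively correlated
#' as they are in real climate normals; MAP is floored at zero. Zone means
#' follow a coast-to-interior gradient; within-zone noise is small relative
#' to between-zone separation (see the methods vignette for the rationale).
#'
#' @param coords data.frame with \code{x_km}, \code{y_km} (and \code{id}).
#' @param seed integer seed.
#' @param n_zones number of latent climate zones (default 4).
#' @param mat_means,map_means zone means for MAT (C) and MAP (mm), recycled
#'   to \code{n_zones}.
#' @param mat_sd,nffd_sd,map_sd within-zone standard deviations.
#' @return list with \code{climate} (data.frame id, MAT, NFFD, MAP),
#'   \code{zone} (integer labels, the ground truth for clustering) and the
#'   zone parameters used.
#' @export
sim_climate <- function(coords, seed, n_zones = 4L,
                        mat_means = c(9, 7, 5, 3),
                        map_means = c(2200, 1500, 1000, 600),
                        mat_sd = 0.6, nffd_sd = 8, map_sd = 120) {
  stopifnot(all(c("x_km", "y_km") %in% names(coords)))
  set.seed(split_seed(seed, "climate"))
  n <- nrow(coords)
  mat_means <- rep_len(mat_means, n_zones)
  map_means <- rep_len(map_means, n_zones)
  km <- kmeans(coords[, c("x_km", "y_km")], centers = n_zones, nstart = 5)
  # order zones along the landscape diagonal so labels are reproducible
  ord <- order(km$centers[, 1] + km$centers[, 2])
  zone <- match(km$cluster, ord)
  MAT <- mat_means[zone] + rnorm(n, 0, mat_sd)
  NFFD <- 60 + 18 * MAT + rnorm(n, 0, nffd_sd)
  MAP <- pmax(map_means[zone] + rnorm(n, 0, map_sd), 0)
  id <- if (!is.null(coords$id)) coords$id else sprintf("ind_%04d", seq_len(n))
  list(climate = data.frame(id = id, MAT = MAT, NFFD = NFFD, MAP = MAP,
                            stringsAsFactors = FALSE),
       zone = zone,
       zone_params = list(mat_means = mat_means, map_means = map_means,
                          mat_sd = mat_sd, nffd_sd = nffd_sd, map_sd = map_sd))
}

#' Simulate clonally replicated phenotypes with known variance components
#'
#' Draws one quantitative trait under the additive animal model: per-genotype
#' breeding values a ~ N(0, sigma2_a G) (via the Cholesky factor of the
#' supplied relationship matrix), among-cluster effects with variance
#' sigma2_p, and i.i.d. residuals per clonal ramet. The planted components
#' are derived from the configured heritability and Q_ST on a unit
#' within-genotype scale: sigma2_a = h2, sigma2_e = 1 - h2, and
#' sigma2_p = 2 sigma2_a Q_ST / (1 - Q_ST) (the Q_ST ratio inverted for the
#' among-group variance). With few clusters the realized among-cluster
#' variance of a random draw would itself be a noisy chi-square draw, so the
#' cluster effects are centered and rescaled to carry exactly sigma2_p
#' (sample variance, d-1 denominator); ramets of a genotype share its
#' breeding value and differ only in residuals.
#'
#' @param G n x n relationship matrix (a [grm] object or plain matrix) for
#'   the genotypes; order defines genotype order.
#' @param clusters integer cluster labels, one per genotype.
#' @param cfg a [sim_config()]; uses \code{h2_true}, \code{qst_true},
#'   \code{n_ramets}, \code{seed}.
#' @param scale_exact center and rescale the cluster effects so their
#'   realized sample variance equals sigma2_p exactly (default TRUE, the
#'   right choice for parameter-recovery studies where "truth" must be
#'   sharp). FALSE draws them as plain N(0, sigma2_p), so the realized
#'   among-cluster variance fluctuates chi-square-like as it would for a
#'   genuinely neutral trait — use this when emulating neutral traits for
#'   calibration.
#' @return list with \code{phenotypes} (data.frame genotype_id, ramet,
#'   trait) and \code{truth} (the exact variance components and effects
#'   used).
#' @export
sim_phenotypes <- function(G, clusters, cfg, scale_exact = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (inherits(G, "grm")) G <- G$G
  n <- nrow(G)
  stopifnot(length(clusters) == n)
  if (cfg$qst_true >= 1) stop("qst_true = 1 implies infinite cluster variance")
  set.seed(split_seed(cfg$seed, "phenotypes"))
  sigma_a2 <- cfg$h2_true
  sigma_e2 <- 1 - cfg$h2_true
  sigma_p2 <- 2 * sigma_a2 * cfg$qst_true / (1 - cfg$qst_true)

  a <- if (sigma_a2 > 0) {
    R <- chol(G + diag(1e-6 * mean(diag(G)), n))
    drop(crossprod(R, rnorm(n))) * sqrt(sigma_a2)
  } else rep(0, n)

  d <- length(unique(clusters))
  u <- rep(0, d)
  if (sigma_p2 > 0) {
    if (d < 2) stop("need >= 2 clusters to plant among-cluster variance")
    u <- rnorm(d, 0, sqrt(sigma_p2))
    if (scale_exact) {
      u <- u - mean(u)
      u <- u * sqrt(sigma_p2 / (sum(u^2) / (d - 1)))
    }
  }
  names(u) <- sort(unique(clusters))

  r <- cfg$n_ramets
  gid <- rep(rownames(G) %||% sprintf("gen_%04d", seq_len(n)), each = r)
  base <- rep(10 + u[as.character(clusters)] + a, each = r)
  y <- base + rnorm(n * r, 0, sqrt(sigma_e2))
  list(phenotypes = data.frame(genotype_id = gid,
                               ramet = rep(seq_len(r), times = n),
                               trait = y, stringsAsFactors = FALSE),
       truth = list(sigma_p2 = sigma_p2, sigma_a2 = sigma_a2,
                    sigma_e2 = sigma_e2, cluster_effects = u,
                    breeding_values = a, config = cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
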