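#' Simulate island-model genotypes with a target F_ST
#'
#' Balding-Nichols generator: each locus draws an ancestral frequency
#' p ~ Uniform(0.05, 0.95); each deme then draws its frequency from
#' Beta(p (1-F)/F, (1-p)(1-F)/F) so that the expected among-deme variance in
#' allele frequency is F p (1-p), and genotypes are Binomial(2, p_deme)
#' (Hardy-Weinberg within demes). \code{target_fst = 0} degenerates cleanly
#' to a single panmictic pool (all demes share the ancestral frequencies).
#'
#' @param cfg a [sim_config()].
#' @return list with \code{genotypes} (a [genotype_matrix()]) and
#'   \code{truth}: deme labels per individual, the ancestral and realized
#'   per-deme allele frequencies, and the config used.
#' @export
sim_island_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(split_seed(cfg$seed, "island"))
  d <- cfg$n_pops; m <- cfg$n_loci; npp <- cfg$n_per_pop
  p0 <- runif(m, 0.05, 0.95)
  F <- cfg$target_fst
  if (F > 0) {
    a <- p0 * (1 - F) / F
    b <- (1 - p0) * (1 - F) / F
    pk <- matrix(rbeta(d * m, rep(a, each = d), rep(b, each = d)),
                 nrow = d, ncol = m)
  } else {
    pk <- matrix(rep(p0, each = d), nrow = d, ncol = m)
  }
  labels <- rep(seq_len(d), each = npp)
  pr <- pk[labels, , drop = FALSE]
  dos <- matrix(rbinom(length(pr), 2L, pr), nrow = d * npp, ncol = m)
  rownames(dos) <- sprintf("ind_%04d", seq_len(nrow(dos)))
  g <- genotype_matrix(dos)
  list(genotypes = g,
       truth = list(cluster_labels = labels, ancestral_freq = p0,
                    deme_freq = pk, config = cfg))
}

#' Simulate isolation-by-distance genotypes on a continuous landscape
#'
#' Individuals are placed uniformly on a square landscape and per-locus
#' allele frequencies follow a spatially autocorrelated Gaussian field with
#' exponential correlation \eqn{\exp(-d/\sigma)} at distance d and
#' correlation scale \code{dispersal_sigma}; the field is scaled so the
#' marginal among-location frequency variance is \code{target_fst} x p(1-p),
#' giving a stepping-stone-like decay of genetic similarity with distance.
#' As \code{dispersal_sigma} grows without bound the field becomes a single
#' shared draw per locus and spatial structure vanishes.
#'
#' @param cfg a [sim_config()]; total sample size is
#'   \code{n_pops * n_per_pop}.
#' @return list with \code{genotypes}, \code{coords} (id, lat, lon, x_km,
#'   y_km) and \code{truth} (expected per-individual frequencies, config).
#' @export
sim_ibd_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(split_seed(cfg$seed, "ibd"))
  n <- cfg$n_pops * cfg$n_per_pop
  m <- cfg$n_loci
  ext <- cfg$landscape_extent
  xy <- cbind(x = runif(n, 0, ext), y = runif(n, 0, ext))
  D <- as.matrix(stats::dist(xy))
  C <- exp(-D / cfg$dispersal_sigma)
  L <- chol(C + diag(1e-8, n))
  z <- crossprod(L, matrix(rnorm(n * m), n, m))   # n x m correlated field
  p0 <- runif(m, 0.05, 0.95)
  F <- max(cfg$target_fst, 1e-6)
  sdv <- sqrt(F * p0 * (1 - p0))
  pr <- pmin(pmax(rep(p0, each = n) + z * rep(sdv, each = n), 0.01), 0.99)
  dos <- matrix(rbinom(n * m, 2L, pr), n, m)
  ids <- sprintf("ind_%04d", seq_len(n))
  rownames(dos) <- ids
  # lat/lon chart anchored in coastal British Columbia so the coordinate
  # preparation step (projection + dedup) can be exercised on simulated data
  lat <- 48 + xy[, "y"] / 111.32
  lon <- -128 + xy[, "x"] / (111.32 * cos(lat * pi / 180))
  coords <- data.frame(id = ids, lat = lat, lon = lon,
                       x_km = xy[, "x"], y_km = xy[, "y"],
                       stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dos), coords = coords,
       truth = list(expected_freq = pr, config = cfg))
}

#' Overwrite loci with climate-driven allele-frequency clines
#'
#' Replaces the last \code{n_clinal_loci} loci of \code{base} (or an
#' explicit locus selection) with genotypes drawn from logistic clinal
#' frequencies \eqn{p_i = logistic(\alpha + s z_i)} where z is the supplied
#' predictor (a climate variable or a spatial coordinate) and s the
#' configured \code{cline_slope} in the predictor's units. Per-locus
#' intercepts are drawn Uniform(-1, 1). Non-clinal loci are untouched.
#'
#' @param base a [genotype_matrix()].
#' @param predictor numeric vector, one value per individual, in the units
#'   the slope refers to (e.g. standardized MAT, or northing in Mm).
#' @param cfg a [sim_config()].
#' @param loci optional locus indices to overwrite (defaults to the last
#'   \code{cfg$n_clinal_loci} columns).
#' @return list with \code{genotypes}, \code{clinal_locus_ids} and the
#'   expected clinal frequencies.
#' @export
sim_clinal_loci <- function(base, predictor, cfg, loci = NULL) {
  stopifnot(inherits(base, "genotype_matrix"), inherits(cfg, "sim_config"))
  n <- nrow(base$dosage); m <- ncol(base$dosage)
  stopifnot(length(predictor) == n)
  k <- cfg$n_clinal_loci
  if (k == 0L)
    return(list(genotypes = base, clinal_locus_ids = character(0),
                expected_freq = NULL))
  if (is.null(loci)) loci <- seq.int(m - k + 1L, m)
  stopifnot(length(loci) == k, all(loci >= 1), all(loci <= m))
  if (cfg$cline_slope == 0)
    warning("cline_slope = 0: overwritten loci are indistinguishable from neutral")
  set.seed(split_seed(cfg$seed, "clinal"))
  alpha <- runif(k, -1, 1)
  pr <- plogis(outer(predictor, rep(cfg$cline_slope, k)) +
                 matrix(alpha, n, k, byrow = TRUE))
  dos <- base$dosage
  dos[, loci] <- rbinom(n * k, 2L, pr)
  list(genotypes = genotype_matrix(dos, base$locus_meta[, c("id", "chrom", "pos")]),
       clinal_locus_ids = colnames(base$dosage)[loci],
       expected_freq = pr)
}
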