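#' Project sampling locations and pick one genotype per location
#'
#' Projects latitude/longitude onto a planar chart in km using an azimuthal
#' equidistant projection about the sample centroid (great-circle faithful
#' at the sampling scale, no UTM zone seams), drops individuals with
#' missing coordinates (logged), and selects one randomly chosen individual
#' per unique (lat, lon) pair, deterministically for a given seed. The
#' function is idempotent on already-deduplicated input.
#'
#' @param coords data.frame with \code{id}, \code{lat}, \code{lon}.
#' @param seed integer seed for the per-location choice.
#' @return list with \code{projected} (id, lat, lon, x_km, y_km for all
#'   usable individuals), \code{representatives} (one row per unique
#'   location), and \code{dropped} (ids with missing coordinates).
#' @export
prepare_locations <- function(coords, seed = 1L) {
  stopifnot(all(c("id", "lat", "lon") %in% names(coords)))
  miss <- is.na(coords$lat) | is.na(coords$lon)
  dropped <- coords$id[miss]
  if (any(miss)) {
    message(sprintf("excluding %d individuals with missing coordinates", sum(miss)))
    coords <- coords[!miss, , drop = FALSE]
  }
  stopifnot(all(coords$lat >= -90 & coords$lat <= 90),
            all(coords$lon >= -180 & coords$lon <= 180))
  ctr <- c(mean(coords$lon), mean(coords$lat))
  pts <- cbind(coords$lon, coords$lat)
  dist_km <- geosphere::distGeo(ctr, pts) / 1000
  brg <- geosphere::bearing(ctr, pts) * pi / 180
  brg[is.na(brg)] <- 0  # point coincides with the centroid
  projected <- data.frame(id = coords$id, lat = coords$lat, lon = coords$lon,
                          x_km = dist_km * sin(brg), y_km = dist_km * cos(brg),
                          stringsAsFactors = FALSE)
  key <- paste(coords$lat, coords$lon, sep = "/")
  set.seed(split_seed(seed, "dedup"))
  pick <- unlist(lapply(split(seq_len(nrow(projected)), key), function(ix) {
    if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
  }), use.names = FALSE)
  pick <- sort(pick)
  list(projected = projected,
       representatives = projected[pick, , drop = FALSE],
       dropped = dropped)
}

#' Spatial connection network over sampling locations
#'
#' Either a K-nearest-neighbour graph (default K = 10, adjacency
#' symmetrized by union, distance ties broken by node order) or a distance
#' band (connected iff lo < d <= hi, in km). Weights are the
#' row-standardized adjacency; rows of isolated nodes are zero and flagged.
#'
#' @param coords data.frame with \code{x_km}, \code{y_km} (e.g. the
#'   representatives from [prepare_locations()]).
#' @param method "knn" or "distance_band".
#' @param k neighbours for knn.
#' @param lo,hi band limits in km for distance_band.
#' @return a \code{spatial_network}: coords, binary adjacency \code{A},
#'   row-standardized weights \code{W}, construction record, isolated
#'   nodes.
#' @export
build_network <- function(coords, method = c("knn", "distance_band"),
                          k = 10L, lo = 0, hi = 200) {
  method <- match.arg(method)
  xy <- as.matrix(coords[, c("x_km", "y_km")])
  n <- nrow(xy)
  D <- as.matrix(dist(xy))
  A <- matrix(0L, n, n)
  if (method == "knn") {
    if (n < k + 1) stop("need at least k + 1 nodes for a knn network")
    if (any(D[upper.tri(D)] == 0))
      stop("coincident nodes: deduplicate locations before building a knn network")
    for (i in seq_len(n)) {
      nb <- setdiff(order(D[i, ]), i)[seq_len(k)]  # ties broken by node order
      A[i, nb] <- 1L
    }
    A <- pmax(A, t(A))  # symmetrize by union
  } else {
    A[D > lo & D <= hi] <- 1L
    diag(A) <- 0L
  }
  rs <- rowSums(A)
  W <- A / ifelse(rs == 0, 1, rs)
  nodes <- if (!is.null(coords$id)) coords$id else as.character(seq_len(n))
  dimnames(A) <- dimnames(W) <- list(nodes, nodes)
  structure(list(coords = coords, A = A, W = W, method = method,
                 params = if (method == "knn") list(k = k) else list(lo = lo, hi = hi),
                 isolated = which(rs == 0)),
            class = "spatial_network")
}

#' Moran's I with a permutation test
#'
#' Computes I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z the
#' centered variable and w the binary adjacency of the network (the lag
#' definition used throughout), its null expectation -1/(n-1), and a
#' one-sided permutation p-value toward the observed side of the
#' expectation (add-one convention).
#'
#' @param x numeric vector over network nodes (non-constant).
#' @param net a [build_network()] result.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param weights "binary" (adjacency, default) or "row" (row-standardized).
#' @return list with \code{I}, \code{expected}, \code{p}, \code{n_perm},
#'   \code{perm_mean}, \code{perm_sd}.
#' @export
morans_i <- function(x, net, n_perm = 999L, seed = 1L,
                     weights = c("binary", "row")) {
  weights <- match.arg(weights)
  W <- if (weights == "binary") net$A else net$W
  n <- length(x)
  stopifnot(n == nrow(W))
  if (sd(x) == 0) stop("zero variance: Moran's I undefined for constant input")
  S0 <- sum(W)
  if (S0 == 0) stop("network has no edges")
  stat <- function(z) {
    z <- z - mean(z)
    (n / S0) * drop(crossprod(z, W %*% z)) / sum(z^2)
  }
  I <- stat(x)
  expected <- -1 / (n - 1)
  set.seed(split_seed(seed, "perm"))
  perms <- vapply(seq_len(n_perm), function(i) stat(sample(x)), 0)
  p <- if (I >= expected) (1 + sum(perms >= I)) / (n_perm + 1)
       else (1 + sum(perms <= I)) / (n_perm + 1)
  list(I = I, expected = expected, p = p, n_perm = n_perm,
       perm_mean = mean(perms), perm_sd = sd(perms))
}

#' Moran's I profile over distance lags
#'
#' Builds successive distance-band networks of width \code{lag_width}
#' (bands \[0, w), \[w, 2w), ... up to the maximum pairwise distance) over
#' the locations and computes [morans_i()] per band; bands with no edges
#' are skipped with a log entry.
#'
#' @param x numeric vector over locations.
#' @param coords data.frame with \code{x_km}, \code{y_km}.
#' @param lag_width band width in km (default 200, the standard lag).
#' @param n_perm,seed passed to [morans_i()].
#' @return data.frame with lag bounds, n_edges, I, expected, p.
#' @export
morans_lag_profile <- function(x, coords, lag_width = 200, n_perm = 999L,
                               seed = 1L) {
  xy <- as.matrix(coords[, c("x_km", "y_km")])
  D <- as.matrix(dist(xy))
  maxd <- max(D)
  breaks <- seq(0, maxd + lag_width, by = lag_width)
  out <- list()
  for (b in seq_len(length(breaks) - 1)) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    A <- matrix(0L, nrow(D), ncol(D))
    A[D >= lo & D < hi] <- 1L
    diag(A) <- 0L
    if (sum(A) == 0) {
      message(sprintf("lag [%g, %g) km has no pairs; skipped", lo, hi))
      next
    }
    net <- structure(list(A = A, W = A / pmax(rowSums(A), 1)),
                     class = "spatial_network")
    mi <- morans_i(x, net, n_perm = n_perm, seed = seed + b)
    out[[length(out) + 1]] <- data.frame(lag_lo = lo, lag_hi = hi,
                                         n_edges = sum(A) / 2, I = mi$I,
                                         expected = mi$expected, p = mi$p)
  }
  do.call(rbind, out)
}

#' Per-locus logistic cline scores (SPA-style)
#'
#' For each polymorphic locus, fits allele presence against the predictors
#' by binomial logistic regression (each diploid contributing two Bernoulli
#' allele draws) and scores the locus by the norm of the slope vector on
#' standardized predictors: a steep allele-frequency cline in space or
#' climate yields a large score. Perfect separation is handled by capping
#' the norm (default 25 on standardized predictors) and flagging the
#' locus. Flags are drawn at the upper 5 and 1 percent quantiles of the
#' score distribution. Slopes are also reported in the predictors' original
#' units so generating slopes can be recovered.
#'
#' @param g a [genotype_matrix()].
#' @param predictors numeric matrix or data.frame, one row per individual
#'   (coordinates, climate variables or their principal components).
#' @param cap norm cap for separated fits.
#' @return data.frame per locus: score, separation flag, original-unit
#'   slopes (\code{slope_*}), \code{flag5}, \code{flag1}.
#' @export
spa_cline_scores <- function(g, predictors, cap = 25) {
  dos <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  Z <- as.matrix(predictors)
  stopifnot(nrow(Z) == nrow(dos))
  sds <- apply(Z, 2, sd)
  if (any(sds == 0)) stop("constant predictor supplied")
  Zs <- scale(Z)
  m <- ncol(dos)
  q <- ncol(Z)
  scores <- numeric(m); sep <- logical(m)
  slopes <- matrix(NA_real_, m, q,
                   dimnames = list(colnames(dos),
                                   paste0("slope_", colnames(Z) %||% paste0("z", 1:q))))
  X <- cbind(1, Zs)
  for (j in seq_len(m)) {
    y <- dos[, j]
    okr <- !is.na(y)
    p <- mean(y[okr]) / 2
    if (p <= 0 || p >= 1) { scores[j] <- NA; next }
    fit <- suppressWarnings(
      glm.fit(X[okr, , drop = FALSE], y[okr] / 2,
              weights = rep(2, sum(okr)), family = binomial()))
    b <- fit$coefficients[-1]
    nrm <- sqrt(sum(b^2))
    if (!fit$converged || !is.finite(nrm) || nrm > cap) {
      sep[j] <- TRUE
      if (!is.finite(nrm) || nrm > cap) {
        b <- b * (cap / max(nrm, cap))
        nrm <- cap
      }
    }
    scores[j] <- nrm
    slopes[j, ] <- b / sds
  }
  q95 <- quantile(scores, 0.95, na.rm = TRUE)
  q99 <- quantile(scores, 0.99, na.rm = TRUE)
  out <- data.frame(id = colnames(dos), score = scores, separation = sep,
                    stringsAsFactors = FALSE)
  out <- cbind(out, slopes)
  out$flag5 <- !is.na(scores) & scores >= q95
  out$flag1 <- !is.na(scores) & scores >= q99
  out
}
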