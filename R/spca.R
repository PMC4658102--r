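#' Spatial principal component analysis of genotypes
#'
#' Eigen-decomposes C = (1 / 2n) X' (W + W') X where X is the
#' column-centered dosage matrix over network nodes and W the
#' row-standardized weight matrix: each axis maximizes the product of
#' genetic variance and spatial autocorrelation of its scores, so large
#' positive eigenvalues indicate global structure (isolation-by-distance
#' clines) and large negative eigenvalues discrete local clusters. For each
#' axis the eigenvalue equals var(score) x Moran's I(score) (I taken with
#' row-standardized weights and S0 = sum of weights).
#'
#' Significance of each type of structure comes from permutation tests that
#' randomly reassign genotype rows to network nodes: the global (local)
#' statistic is the sum of positive (absolute negative) eigenvalues,
#' compared to its permutation distribution with the add-one convention.
#'
#' @param g a [genotype_matrix()] (individuals aligned with network nodes).
#' @param net a [build_network()] result.
#' @param n_perm permutations for the structure tests (>= 99).
#' @param seed integer seed.
#' @param n_axes how many leading/trailing scores to return.
#' @return an \code{spca_result}: eigenvalues (descending), scores for the
#'   retained axes, global_p, local_p, the permutation statistics, n_perm.
#' @export
spca <- function(g, net, n_perm = 199L, seed = 1L, n_axes = 5L) {
  if (n_perm < 99) stop("structure tests need at least 99 permutations")
  dos <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  n <- nrow(dos)
  stopifnot(nrow(net$W) == n)
  X <- scale(dos, center = TRUE, scale = FALSE)
  if (anyNA(X)) X[is.na(X)] <- 0  # mean imputation after centering
  H <- (net$W + t(net$W)) / (2 * n)

  # dual-space trick: nonzero eigenvalues of X'HX equal those of D U'HU D
  sv <- svd(X, nu = min(n, ncol(X)), nv = 0)
  r <- sum(sv$d > max(sv$d) * 1e-10)
  U <- sv$u[, seq_len(r), drop = FALSE]
  Dg <- sv$d[seq_len(r)]

  eig_of <- function(Hm, vectors = FALSE) {
    S <- crossprod(U, Hm %*% U) * tcrossprod(Dg)  # D U'HU D, symmetric
    eigen((S + t(S)) / 2, symmetric = TRUE, only.values = !vectors)
  }
  ee <- eig_of(H, vectors = TRUE)
  values <- ee$values
  # scores = X v = U D w for eigenvectors w of the dual problem
  take <- unique(c(seq_len(min(n_axes, r)),
                   seq.int(max(r - n_axes + 1, 1), r)))
  scores <- U %*% (ee$vectors[, take, drop = FALSE] * Dg)
  colnames(scores) <- paste0("axis", take)
  rownames(scores) <- rownames(dos)

  g_stat <- function(v) sum(v[v > 0])
  l_stat <- function(v) sum(abs(v[v < 0]))
  set.seed(split_seed(seed, "perm"))
  perm_g <- numeric(n_perm); perm_l <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    pidx <- sample.int(n)
    v <- eig_of(H[pidx, pidx])$values
    perm_g[i] <- g_stat(v); perm_l[i] <- l_stat(v)
  }
  structure(list(eigenvalues = values, scores = scores,
                 global_stat = g_stat(values), local_stat = l_stat(values),
                 global_p = (1 + sum(perm_g >= g_stat(values))) / (n_perm + 1),
                 local_p = (1 + sum(perm_l >= l_stat(values))) / (n_perm + 1),
                 perm_global = perm_g, perm_local = perm_l,
                 n_perm = n_perm),
            class = "spca_result")
}

#' @export
print.spca_result <- function(x, ...) {
  v <- x$eigenvalues
  cat(sprintf(
    "sPCA: %d axes; leading eigenvalue %.4g, trailing %.4g\n  global test p = %.4g, local test p = %.4g (%d permutations)\n",
    length(v), v[1], v[length(v)], x$global_p, x$local_p, x$n_perm))
  invisible(x)
}
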