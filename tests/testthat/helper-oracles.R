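# Independent oracle implementations: deliberately naive (loops, direct
# formulas) so they share no code path with the package internals.

# restricted log-likelihood evaluated directly from its definition
oracle_reml_loglik <- function(theta, y, X, Vs) {
  n <- length(y); p <- ncol(X)
  V <- matrix(0, n, n)
  for (i in seq_along(Vs)) V <- V + theta[i] * Vs[[i]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       drop(t(y) %*% P %*% y)))
}

# brute-force REML: coarse grid then polish with optim on log-variances
oracle_reml_max <- function(y, X, Vs) {
  f <- function(lt) -oracle_reml_loglik(exp(lt), y, X, Vs)
  vy <- var(y)
  grid <- expand.grid(rep(list(log(vy * c(0.05, 0.3, 1, 3))), length(Vs)))
  best <- NULL; bval <- Inf
  for (i in seq_len(nrow(grid))) {
    v <- f(as.numeric(grid[i, ]))
    if (v < bval) { bval <- v; best <- as.numeric(grid[i, ]) }
  }
  op <- optim(best, f, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-14))
  op <- optim(op$par, f, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14))
  list(loglik = -op$value, theta = exp(op$par))
}

# direct double-loop VanRaden GRM
oracle_grm <- function(M) {
  n <- nrow(M); m <- ncol(M)
  p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  M <- M[, keep, drop = FALSE]; p <- p[keep]
  denom <- 2 * sum(p * (1 - p))
  G <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- 0
    for (l in seq_along(p)) s <- s + (M[i, l] - 2 * p[l]) * (M[j, l] - 2 * p[l])
    G[i, j] <- s / denom
  }
  G
}

# literal Weir & Cockerham (1984) theta for one biallelic locus from
# per-population sample sizes, allele frequencies and het. proportions
oracle_wc_theta <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# double-loop Moran's I with binary weights
oracle_moran <- function(x, A) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0; S0 <- 0
  for (i in 1:n) for (j in 1:n) {
    num <- num + A[i, j] * z[i] * z[j]
    S0 <- S0 + A[i, j]
  }
  (n / S0) * num / sum(z^2)
}

# binomial log-likelihood of a fitted logistic model, evaluated directly
oracle_logit_ll <- function(beta, X, y_prop, w) {
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  sum(w * (y_prop * log(mu) + (1 - y_prop) * log(1 - mu)))
}

# small deterministic genotype panel used by several tests
toy_panel <- function(n = 12, m = 8, seed = 99) {
  set.seed(seed)
  dos <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(1:m, each = n)]),
                n, m)
  genotype_matrix(dos)
}
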