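#' Mixed-model specification
#'
#' A linear mixed model y = X b + sum_i Z_i u_i + e with u_i ~ N(0,
#' sigma2_i K_i) and e ~ N(0, sigma2_e I). Each random term supplies an
#' incidence matrix Z and an optional covariance K (identity when NULL,
#' e.g. a relationship matrix for an additive genetic term).
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (an intercept column at minimum);
#'   must have full column rank.
#' @param random named list of random terms, each a list with elements
#'   \code{Z} (n x q incidence) and optional \code{K} (q x q PSD
#'   covariance).
#' @return a \code{mm_spec} object.
#' @export
mm_spec <- function(y, X, random) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(random) >= 1)
  if (is.null(names(random)) || any(names(random) == ""))
    names(random) <- paste0("u", seq_along(random))
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design X is rank deficient")
  for (term in random) {
    stopifnot(nrow(term$Z) == n)
    if (!is.null(term$K)) stopifnot(nrow(term$K) == ncol(term$Z))
  }
  structure(list(y = y, X = X, random = random), class = "mm_spec")
}

## Incidence matrix for a factor (levels in sorted order)
#' Build a 0/1 incidence matrix mapping observations to factor levels
#' @param f a factor or vector coercible to one
#' @return n x nlevels indicator matrix with level column names
#' @export
incidence <- function(f) {
  f <- factor(f)
  Z <- model.matrix(~ f - 1)
  colnames(Z) <- levels(f)
  Z
}

#' Restricted log-likelihood of a variance-parameter vector
#'
#' Evaluates the REML log-likelihood
#' \deqn{-\tfrac12\{(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| + y'Py\}}
#' at the supplied variance components (last element = residual variance).
#' Used internally by [reml_fit()]; exposed because direct evaluation over a
#' parameter grid is a convenient independent check of the optimizer.
#'
#' @param theta non-negative variance components, one per random term plus
#'   the residual (last).
#' @param spec a [mm_spec()].
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(theta, spec) {
  parts <- reml_parts(theta, spec)
  parts$ll
}

## V_i builders: list of n x n covariance contributors, residual last
vbuild <- function(spec) {
  Vs <- lapply(spec$random, function(term) {
    if (is.null(term$K)) tcrossprod(term$Z)
    else term$Z %*% term$K %*% t(term$Z)
  })
  Vs$residual <- diag(length(spec$y))
  Vs
}

## Core REML quantities at theta: loglik, P y, P, per-component traces
reml_parts <- function(theta, spec, Vs = vbuild(spec)) {
  n <- length(spec$y); X <- spec$X; p <- ncol(X)
  V <- Reduce(`+`, Map(`*`, Vs, theta))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  Vinv <- chol2inv(ch)
  XtVX <- crossprod(X, Vinv %*% X)
  chx <- chol(XtVX)
  B <- Vinv %*% X %*% chol2inv(chx)      # V^-1 X (X'V^-1X)^-1
  P <- Vinv - B %*% crossprod(X, Vinv)
  Py <- P %*% spec$y
  ll <- -0.5 * ((n - p) * log(2 * pi) +
                  2 * sum(log(diag(ch))) +
                  2 * sum(log(diag(chx))) +
                  drop(crossprod(spec$y, Py)))
  list(ll = ll, P = P, Py = Py)
}

#' REML estimation of variance components
#'
#' Fits the variance components of a [mm_spec()] by restricted maximum
#' likelihood: a short expectation-maximization warm-up followed by
#' average-information (AI) updates with step halving, converging when the
#' relative change in restricted log-likelihood falls below \code{tol} and
#' the gradient over free components is numerically zero. Components driven
#' negative are clamped to the zero boundary (active-set); standard errors
#' are undefined there. The response is standardized internally so
#' convergence is invariant to the trait's scale, and estimates and
#' log-likelihood are reported on the original scale.
#'
#' Confounded designs (a random term whose marginal covariance is
#' numerically proportional to another term's, e.g. an additive term with
#' identity relationship and no replication against the residual) are
#' detected up front and refused.
#'
#' @param spec a [mm_spec()].
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum iterations.
#' @return an object of class \code{varcomp}: list with \code{estimates}
#'   (named, residual last), \code{vcov} (asymptotic covariance from the AI
#'   matrix; NA rows for boundary components), \code{converged},
#'   \code{n_iter}, \code{loglik}, \code{boundary} flags, \code{n},
#'   \code{rank_X}.
#' @export
reml_fit <- function(spec, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(spec, "mm_spec"))
  n <- length(spec$y); p <- ncol(spec$X)
  k <- length(spec$random) + 1L
  if (n <= p + k) stop("too few observations for the number of components")

  s <- sd(spec$y)
  if (s == 0) stop("constant response")
  sspec <- spec; sspec$y <- spec$y / s
  Vs <- vbuild(sspec)

  # confounding check: proportional covariance structures are unidentifiable
  vecs <- vapply(Vs, function(V) as.numeric(V), numeric(n * n))
  cc <- crossprod(scale(vecs, center = TRUE, scale = FALSE))
  dg <- sqrt(diag(cc))
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    if (dg[i] > 0 && dg[j] > 0 && abs(cc[i, j] / (dg[i] * dg[j])) > 1 - 1e-10)
      stop(sprintf("random terms '%s' and '%s' are confounded (proportional covariance)",
                   names(Vs)[i], names(Vs)[j]))
  }

  qlev <- c(vapply(sspec$random, function(t) ncol(t$Z), 0), n)
  vy <- var(sspec$y)
  theta <- rep(vy / k, k)
  lb <- 1e-10 * vy

  parts <- reml_parts(theta, sspec, Vs)
  ll <- parts$ll
  grad_info <- function(parts) {
    Py <- parts$Py; P <- parts$P
    # V_i symmetric, so tr(P V_i) = sum(P * V_i): no matrix product needed
    gr <- vapply(seq_len(k), function(i) {
      -0.5 * (sum(P * Vs[[i]]) - drop(crossprod(Py, Vs[[i]] %*% Py)))
    }, 0)
    VPy <- vapply(Vs, function(V) as.numeric(V %*% Py), numeric(n))
    AI <- 0.5 * crossprod(VPy, P %*% VPy)
    list(gr = gr, AI = AI)
  }

  n_em <- 4L
  it <- 0L; converged <- FALSE
  gi <- grad_info(parts)
  repeat {
    it <- it + 1L
    if (it <= n_em) {
      # EM-REML update (robust, keeps components positive)
      new_theta <- vapply(seq_len(k), function(i) {
        theta[i] + theta[i]^2 / qlev[i] * 2 * gi$gr[i]
      }, 0)
      new_theta <- pmax(new_theta, lb)
      np <- reml_parts(new_theta, sspec, Vs)
      if (np$ll > ll - 1e-12) {
        theta <- new_theta; parts <- np; ll <- np$ll; gi <- grad_info(parts)
      }
    } else {
      free <- !(theta <= lb & gi$gr < 0)
      if (!any(free)) { converged <- TRUE; break }
      d <- rep(0, k)
      AIf <- gi$AI[free, free, drop = FALSE]
      sol <- tryCatch(solve(AIf, gi$gr[free]), error = function(e) NULL)
      if (is.null(sol)) sol <- gi$gr[free] / diag(AIf)
      d[free] <- sol
      step <- 1
      repeat {
        cand <- pmax(theta + step * d, lb)
        np <- reml_parts(cand, sspec, Vs)
        if (np$ll >= ll - 1e-12 || step < 1e-8) break
        step <- step / 2
      }
      if (np$ll < ll - 1e-12) { converged <- TRUE; break }  # no uphill step left
      dl <- np$ll - ll
      theta <- cand; parts <- np; ll <- np$ll
      gi <- grad_info(parts)
      gnorm <- sqrt(sum(gi$gr[!(theta <= lb & gi$gr < 0)]^2))
      if (abs(dl) / (abs(ll) + 1) < tol && gnorm < 1e-6 * n) {
        converged <- TRUE; break
      }
    }
    if (it >= max_iter) break
  }

  boundary <- theta <= lb * 1.01
  theta_out <- ifelse(boundary, 0, theta) * s^2
  names(theta_out) <- names(Vs)
  free <- !boundary
  vc <- matrix(NA_real_, k, k, dimnames = list(names(Vs), names(Vs)))
  if (any(free)) {
    AIf <- gi$AI[free, free, drop = FALSE]
    vinv <- tryCatch(solve(AIf), error = function(e) NULL)
    if (!is.null(vinv)) vc[free, free] <- vinv * s^4
  }
  structure(list(estimates = theta_out, vcov = vc,
                 converged = converged, n_iter = it,
                 loglik = ll - (n - p) * log(s),
                 boundary = boundary, n = n, rank_X = p),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat("REML variance components",
      if (!x$converged) "(NOT converged)" else "", "\n")
  est <- x$estimates
  se <- sqrt(pmax(diag(x$vcov), 0))
  for (i in seq_along(est))
    cat(sprintf("  %-10s %10.5f  (SE %s)%s\n", names(est)[i], est[i],
                ifelse(is.na(se[i]), "-", sprintf("%.5f", se[i])),
                if (x$boundary[i]) " [boundary]" else ""))
  cat(sprintf("  logLik(restricted) = %.6f, %d iterations\n",
              x$loglik, x$n_iter))
  invisible(x)
}
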