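#' Per-locus Weir-Cockerham F_ST among populations
#'
#' The 1984 theta estimator from its three variance components: for each
#' biallelic locus, a (among populations), b (among individuals within
#' populations) and c (within individuals) are computed from the per-deme
#' sample sizes, allele frequencies and observed heterozygosities, and
#' theta = a / (a + b + c). Per-locus estimates may be slightly negative.
#' The multi-locus F_ST is the ratio of summed components (sum a over
#' sum a+b+c), the standard combined estimator. Expected heterozygosity is
#' computed from the pooled allele frequency, so it lies in \[0, 0.5\].
#'
#' Loci need at least two populations with two or more non-missing
#' genotypes; others are reported as NA and counted. Loci monomorphic
#' across all populations have undefined theta (NA).
#'
#' @param g a [genotype_matrix()] or plain dosage matrix.
#' @param pops population labels, one per individual.
#' @return a \code{fst_table}: data.frame (id, fst, he, a, bc) with
#'   attributes \code{multilocus} (ratio-of-sums theta), \code{pops},
#'   \code{n_skipped}.
#' @export
weir_cockerham_fst <- function(g, pops) {
  dos <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  stopifnot(length(pops) == nrow(dos))
  pops <- factor(pops)
  r <- nlevels(pops)
  if (r < 2) stop("need >= 2 populations")
  m <- ncol(dos)

  # per-population, per-locus counts (r x m matrices)
  ok <- !is.na(dos)
  n_i <- rowsum(ok + 0, pops)                      # genotypes observed
  sum_dos <- rowsum(ifelse(ok, dos, 0), pops)
  het <- rowsum(ifelse(ok, (dos == 1) + 0, 0), pops)

  usable <- n_i >= 2
  pops_used <- colSums(usable)
  skip <- pops_used < 2
  n_i[!usable] <- 0; sum_dos[!usable] <- 0; het[!usable] <- 0

  p_i <- ifelse(n_i > 0, sum_dos / (2 * n_i), 0)
  h_i <- ifelse(n_i > 0, het / n_i, 0)
  r_eff <- pops_used
  n_tot <- colSums(n_i)
  nbar <- n_tot / r_eff
  nc <- (n_tot - colSums(n_i^2) / n_tot) / (r_eff - 1)
  pbar <- colSums(n_i * p_i) / n_tot
  s2 <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r_eff - 1) * nbar)
  hbar <- colSums(n_i * h_i) / n_tot

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r_eff - 1) / r_eff * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r_eff - 1) / r_eff * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  mono <- pbar <= 0 | pbar >= 1
  theta <- ifelse(mono | skip, NA_real_, a / (a + b + cc))
  a[mono | skip] <- NA; b[mono | skip] <- NA; cc[mono | skip] <- NA
  he <- 2 * pbar * (1 - pbar)
  he[skip] <- NA

  ids <- colnames(dos) %||% sprintf("snp_%05d", seq_len(m))
  out <- data.frame(id = ids, fst = theta, he = he, a = a, bc = b + cc,
                    stringsAsFactors = FALSE)
  keep <- !is.na(a)
  attr(out, "multilocus") <- sum(a[keep]) / sum(a[keep] + out$bc[keep])
  attr(out, "pops") <- levels(pops)
  attr(out, "n_skipped") <- sum(skip)
  class(out) <- c("fst_table", "data.frame")
  out
}

#' Multi-locus F_ST of an fst_table (ratio of summed components)
#' @param x an \code{fst_table}
#' @param subset optional logical/integer subset of loci
#' @return scalar theta
#' @export
multilocus_fst <- function(x, subset = NULL) {
  if (!is.null(subset)) x <- x[subset, , drop = FALSE]
  keep <- !is.na(x$a)
  sum(x$a[keep]) / sum(x$a[keep] + x$bc[keep])
}

#' Coalescent island-model null for F_ST outlier detection
#'
#' Simulates neutral (He, F_ST) pairs under a symmetric island model via the
#' structured coalescent with infinite-alleles mutation: d of
#' \code{n_demes} demes are sampled at \code{genes_per_deme} genes each,
#' genealogies are generated event by event (within-deme coalescence,
#' migration, mutation — a lineage's leaves receive the allele of the first
#' mutation above them, so lineages terminate at mutation), alleles are
#' collapsed to biallelic (most frequent vs rest), genes are randomly paired
#' into diploids within demes (Hardy-Weinberg) and scored with the same
#' Weir-Cockerham components as observed panels. The migration rate is first
#' set from the island-model approximation F = 1/(1 + 4Nm) and then
#' corrected by pilot runs until the realized multi-locus F_ST is within 5
#' percent of target. Per-locus mutation rates are drawn log-uniformly so
#' collapsed heterozygosities span the observed range; loci with pooled
#' He below \code{he_min} are discarded as array-like ascertainment.
#'
#' @param target_mean_fst target multi-locus F_ST in (0, 1).
#' @param d number of sampled demes (= observed populations).
#' @param genes_per_deme genes sampled per deme (default 50, i.e. 25
#'   diploids).
#' @param n_demes total demes in the island model.
#' @param n_sims simulated loci retained.
#' @param seed integer seed.
#' @param he_min minimum pooled expected heterozygosity retained.
#' @param pilot pilot loci per calibration round.
#' @param max_pilot_rounds calibration rounds allowed.
#' @param M optional scaled migration rate (4Nm); when supplied the pilot
#'   calibration is skipped and this rate is used directly (useful for
#'   drawing further loci from an already calibrated process).
#' @return list with \code{pairs} (data.frame he, fst, plus a/bc
#'   components), \code{M_used} (scaled migration rate 4Nm),
#'   \code{achieved_mean_fst}, the config, and the seed.
#' @export
island_null_simulate <- function(target_mean_fst, d, genes_per_deme = 50L,
                                 n_demes = 100L, n_sims = 200000L, seed = 1L,
                                 he_min = 0.02, pilot = 2000L,
                                 max_pilot_rounds = 3L, M = NULL) {
  stopifnot(target_mean_fst > 0, target_mean_fst < 1, d >= 2, d <= n_demes,
            genes_per_deme %% 2 == 0)
  set.seed(split_seed(seed, "coalescent"))
  # pairwise coalescence times scale with the number of demes, so the
  # mutation-rate window does too: this keeps the collapsed biallelic He
  # spread over (he_min, 0.5] for any island size
  u_lo <- 0.05 / n_demes; u_hi <- 5 / n_demes

  run <- function(M, n) {
    counts <- island_coalescent_cpp(as.integer(n), as.integer(d),
                                    as.integer(genes_per_deme),
                                    as.integer(n_demes), M, u_lo, u_hi,
                                    he_min)
    wc_from_counts(counts, genes_per_deme %/% 2L)
  }

  # island-model closed form as the starting point, then secant correction
  if (is.null(M)) {
    M <- (1 - target_mean_fst) / target_mean_fst
    for (round in seq_len(max_pilot_rounds)) {
      pp <- run(M, pilot)
      achieved <- attr(pp, "multilocus")
      if (abs(achieved - target_mean_fst) / target_mean_fst <= 0.05) break
      # F = 1/(1 + cM)  =>  fit c at the realized point, re-solve for target
      chat <- (1 / achieved - 1) / M
      M <- (1 / target_mean_fst - 1) / chat
    }
  }
  pairs <- run(M, n_sims)
  list(pairs = pairs, M_used = M,
       achieved_mean_fst = attr(pairs, "multilocus"),
       config = list(d = d, genes_per_deme = genes_per_deme,
                     n_demes = n_demes, n_sims = n_sims, he_min = he_min),
       seed = seed)
}

## Weir-Cockerham components from the coalescent output: a matrix with, per
## locus, d major-allele gene counts followed by d heterozygote counts after
## random pairing into n_dip diploids per deme.
wc_from_counts <- function(counts, n_dip) {
  d <- ncol(counts) %/% 2L
  al <- counts[, seq_len(d), drop = FALSE]
  het <- counts[, d + seq_len(d), drop = FALSE]
  r <- d
  n_i <- n_dip
  p_i <- al / (2 * n_dip)
  h_i <- het / n_dip
  n_tot <- r * n_dip
  nbar <- n_dip
  nc <- (n_tot - r * n_dip^2 / n_tot) / (r - 1)
  pbar <- rowMeans(p_i)
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowMeans(h_i)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  out <- data.frame(he = 2 * pbar * (1 - pbar), fst = a / (a + b + cc),
                    a = a, bc = b + cc)
  attr(out, "multilocus") <- sum(a) / sum(a + b + cc)
  out
}

#' Heterozygosity-conditioned neutral F_ST envelope
#'
#' Partitions simulated neutral (He, F_ST) pairs into equal-count He bins
#' and takes the empirical (1-ci)/2 and 1-(1-ci)/2 F_ST quantiles per bin;
#' the curves are linearly interpolated between bin centers (median He per
#' bin) and extrapolated flat beyond them.
#'
#' @param sim_pairs data.frame with \code{he} and \code{fst} (from
#'   [island_null_simulate()]).
#' @param ci confidence level in (0.5, 1), default 0.99.
#' @param n_bins equal-count He bins (default 20).
#' @return an \code{fst_envelope}: he_grid, lower, upper, ci,
#'   mean_neutral_fst (multi-locus over the simulated pairs), n_sims.
#' @export
conditional_envelope <- function(sim_pairs, ci = 0.99, n_bins = 20L) {
  if (ci <= 0.5 || ci >= 1) stop("ci must be in (0.5, 1)")
  n <- nrow(sim_pairs)
  if (ci >= 0.99 && n < 10000)
    stop("need >= 10,000 simulated pairs for a 99% envelope")
  ord <- order(sim_pairs$he)
  he <- sim_pairs$he[ord]; fst <- sim_pairs$fst[ord]
  bin <- ceiling(seq_along(he) / (n / n_bins))
  alpha <- (1 - ci) / 2
  he_grid <- tapply(he, bin, median)
  lower <- tapply(fst, bin, quantile, probs = alpha, names = FALSE)
  upper <- tapply(fst, bin, quantile, probs = 1 - alpha, names = FALSE)
  ml <- if (!is.null(sim_pairs$a)) sum(sim_pairs$a) / sum(sim_pairs$a + sim_pairs$bc)
        else mean(fst)
  structure(list(he_grid = as.numeric(he_grid), lower = as.numeric(lower),
                 upper = as.numeric(upper), ci = ci,
                 mean_neutral_fst = ml, n_sims = n),
            class = "fst_envelope")
}

#' Evaluate envelope bounds at given heterozygosities
#' @param env an \code{fst_envelope}
#' @param he numeric vector of expected heterozygosities
#' @return data.frame with \code{lower} and \code{upper}
#' @export
envelope_bounds <- function(env, he) {
  data.frame(
    lower = approx(env$he_grid, env$lower, xout = he, rule = 2)$y,
    upper = approx(env$he_grid, env$upper, xout = he, rule = 2)$y)
}

#' F_ST outlier detection with iterative neutral-mean trimming
#'
#' Fdist-style loop: (1) simulate the island-model null at the current mean
#' F_ST, (2) build the He-conditioned envelope, (3) flag observed loci
#' outside it (high = candidate diversifying, low = candidate balancing),
#' (4) recompute the multi-locus mean over unflagged loci; repeat until the
#' flagged set stabilizes or \code{max_rounds} is hit (then a warning flag
#' is set). Returns the flags and the trimmed neutral F_ST vector that
#' feeds the Q_ST-F_ST neutrality test.
#'
#' @param obs an \code{fst_table} from [weir_cockerham_fst()].
#' @param d number of sampled demes for the null (defaults to the number of
#'   populations in \code{obs}).
#' @param ci envelope confidence level.
#' @param n_sims simulated loci per round.
#' @param n_demes,genes_per_deme island-model configuration.
#' @param max_rounds trimming rounds allowed (default 5).
#' @param seed integer seed (each round derives its own stream).
#' @return list with \code{flags} (data.frame id, fst, he, flag in
#'   none/high/low), \code{neutral_fst} (per-locus F_ST of unflagged loci,
#'   negatives truncated at 0), \code{trimmed_mean}, \code{rounds},
#'   \code{converged}, \code{envelope}, \code{null}.
#' @export
detect_outliers <- function(obs, d = NULL, ci = 0.99, n_sims = 20000L,
                            n_demes = 100L, genes_per_deme = 50L,
                            max_rounds = 5L, seed = 1L) {
  stopifnot(inherits(obs, "fst_table"), nrow(obs) > 0)
  if (is.null(d)) d <- length(attr(obs, "pops"))
  usable <- !is.na(obs$fst)
  flag <- rep("none", nrow(obs))
  mean_fst <- multilocus_fst(obs)
  prev <- NULL; converged <- FALSE; env <- NULL; null <- NULL
  for (round in seq_len(max_rounds)) {
    null <- island_null_simulate(mean_fst, d, genes_per_deme, n_demes,
                                 n_sims, seed = seed + 131L * round)
    env <- conditional_envelope(null$pairs, ci = ci)
    b <- envelope_bounds(env, obs$he)
    flag <- ifelse(!usable, "none",
                   ifelse(obs$fst > b$upper, "high",
                          ifelse(obs$fst < b$lower, "low", "none")))
    mean_fst <- multilocus_fst(obs, usable & flag == "none")
    if (identical(flag, prev)) { converged <- TRUE; break }
    prev <- flag
  }
  if (!converged)
    warning("outlier set did not stabilize within max_rounds; returning last iteration")
  keep <- usable & flag == "none"
  list(flags = data.frame(id = obs$id, fst = obs$fst, he = obs$he,
                          flag = flag, stringsAsFactors = FALSE),
       neutral_fst = pmax(obs$fst[keep], 0),
       trimmed_mean = mean_fst, rounds = round, converged = converged,
       envelope = env, null = null)
}

#' Chromosome hotspot test for outlier loci
#'
#' Goodness-of-fit of per-chromosome outlier counts against a uniform
#' expectation (total / n_chromosomes), plus a randomization rule for
#' declaring hotspots: the same total is scattered uniformly n_perm times,
#' the maximum per-chromosome count of each replicate is recorded, and a
#' chromosome is a hotspot when its observed count is at least the maximum
#' such count seen across all replicates.
#'
#' @param chrom chromosome label per outlier locus.
#' @param n_chromosomes number of chromosomes considered.
#' @param n_perm randomization replicates (default 1000).
#' @param seed integer seed.
#' @return list with \code{chi2}, \code{df} (= n_chromosomes - 1), \code{p},
#'   \code{counts}, \code{perm_max} (hotspot threshold), \code{hotspots}.
#' @export
hotspot_test <- function(chrom, n_chromosomes, n_perm = 1000L, seed = 1L) {
  if (length(chrom) == 0) stop("no outlier loci supplied")
  if (!is.numeric(chrom)) chrom <- as.integer(factor(chrom))
  chrom <- as.integer(chrom)
  stopifnot(all(chrom >= 1), all(chrom <= n_chromosomes))
  counts <- tabulate(chrom, nbins = n_chromosomes)
  total <- sum(counts)
  expected <- total / n_chromosomes
  chi2 <- sum((counts - expected)^2 / expected)
  df <- n_chromosomes - 1L
  p <- pchisq(chi2, df, lower.tail = FALSE)
  set.seed(split_seed(seed, "hotspot"))
  sims <- rmultinom(n_perm, total, rep(1 / n_chromosomes, n_chromosomes))
  perm_max <- max(apply(sims, 2, max))
  list(chi2 = chi2, df = df, p = p, counts = counts, perm_max = perm_max,
       hotspots = which(counts >= perm_max))
}

#' Pairwise composite linkage disequilibrium (genotypic r^2)
#'
#' Squared Pearson correlation of dosages between loci (pairwise-complete
#' observations); monomorphic loci yield NA rows/columns; the diagonal is 1.
#'
#' @param g a [genotype_matrix()].
#' @param loci locus ids or indices to include.
#' @return symmetric r^2 matrix.
#' @export
pairwise_ld_r2 <- function(g, loci = NULL) {
  dos <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  if (!is.null(loci)) dos <- dos[, loci, drop = FALSE]
  variable <- apply(dos, 2, function(x) {
    x <- x[!is.na(x)]; length(unique(x)) > 1
  })
  r2 <- matrix(NA_real_, ncol(dos), ncol(dos),
               dimnames = list(colnames(dos), colnames(dos)))
  if (any(variable)) {
    cc <- suppressWarnings(cor(dos[, variable, drop = FALSE],
                               use = "pairwise.complete.obs"))
    r2[variable, variable] <- cc^2
  }
  diag(r2) <- ifelse(variable, 1, NA_real_)
  r2
}
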