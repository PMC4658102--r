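---
title: "Methods: quantitative-genetic and landscape-genomic tests of local adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative-genetic and landscape-genomic tests of local adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qstfst)
```

This vignette explains the statistical machinery in `qstfst`, the choices
made where several defensible constructions exist, and what the synthetic
data do and do not establish about behaviour on real data. The package
targets the common design in forest-tree landscape genomics: several
hundred genotypes sampled across a large, climatically heterogeneous range,
genotyped on a SNP array, cloned into a common garden, and grouped into a
handful of climate-defined subpopulations with very low marker
differentiation (multi-locus F_ST on the order of 0.01).

## The mixed models and their derived ratios

All variance components come from one REML engine (`reml_fit()`) applied to
three model forms on the same phenotype records.

**Narrow-sense Q_ST** uses the animal model
$$y = X\beta + Z p + Z a + e, \qquad
p \sim N(0, \sigma^2_p I_d),\quad a \sim N(0, \sigma^2_a G),\quad
e \sim N(0, \sigma^2_e I),$$
with $G = ZZ'/2\sum p_l(1-p_l)$ the realized (VanRaden) relationship matrix
from centered dosages (`compute_grm()`). Then
$$Q_{ST} = \frac{\hat\sigma^2_p}{\hat\sigma^2_p + 2\hat\sigma^2_a}.$$

**Broad-sense Q_ST** exploits clonal replication instead of markers: the
additive term is replaced by a clone term with identity covariance, whose
variance is the total genetic variance; the ramet-within-clone residual
supplies the error. With a single ramet everywhere clone and residual are
confounded, and the fit refuses the model rather than returning arbitrary
numbers. The same confounding guard protects the animal model: an additive
term whose marginal covariance is numerically proportional to another
term's (e.g. $G \approx I$ without replication) is detected up front. This
matters in practice: for a few hundred *unrelated* genotypes the realized
GRM is close to identity, and genetic variance is identified by the clonal
replication, not by the relationship matrix.

**Heritability and P_ST** come from a pair of fits: cluster-as-fixed with
the GRM additive term gives $h^2 = \hat\sigma^2_a/(\hat\sigma^2_a +
\hat\sigma^2_e)$; cluster-as-random with no genetic term gives
$\hat\sigma^2_p$ and $\hat\sigma^2_e$ (individuals within cluster absorbed
into the error); these are assembled as
$$P_{ST} = \frac{\hat\sigma^2_p}{\hat\sigma^2_p + 2 h^2 \hat\sigma^2_e}.$$
The two fits' residual variances mean different things, and the assembled
ratio mixes them deliberately — it is reported exactly as defined, and
flagged degenerate when $h^2 = 0$ (the ratio pins at 1 for any positive
cluster variance).

**The REML engine.** Four expectation-maximization warm-up steps followed
by average-information updates with step halving; convergence when the
relative restricted-log-likelihood change falls below `tol` (default 1e-8)
and the free-component gradient is numerically zero. Negative proposals are
clamped to the zero boundary with an active set; standard errors are
undefined there. The response is standardized internally, which makes
convergence (and all variance ratios) exactly invariant to the trait's
scale. The asymptotic covariance is the inverse AI matrix at the optimum;
ratio standard errors use the delta method. The test suite pins the engine
to three independent oracles: the closed-form residual fit, balanced
one-way ANOVA identities, and direct grid-plus-polish maximization of the
restricted likelihood on random small instances (agreement to 1e-6).

## The Q_ST–F_ST neutrality test

The question is whether a trait's among-cluster differentiation exceeds
what drift alone, at the markers' F_ST, would produce. The null
distribution of $Q_{ST} - F_{ST}$ for a neutral trait is simulated
(`simulate_neutral_null()`): each replicate draws a marker F from the
trimmed neutral F_ST vector, converts it to an among-cluster variance
$\sigma^2_B = 2\hat\sigma^2_a F/(1-F)$, and then mimics *estimation* of
both variances before forming the ratio.

The estimation step is where a naive construction fails. Scaling
$\sigma^2_B$ by $\chi^2_{d-1}/(d-1)$ captures only the drift fluctuation of
the $d$ true cluster effects. But cluster means are estimated from finite
samples: with $n$ genotypes per cluster and genotypic-mean variance
$w = \sigma^2_a + \sigma^2_e/r$ ($r$ ramets), the between mean square is
$(n\sigma^2_B + w)\,\chi^2_{d-1}/(d-1)$ and the within mean square
$w\,\chi^2_{d(n-1)}/d(n-1)$; the simulated estimate is their difference
over $n$, truncated at zero like the REML boundary. At $F_{ST} \approx
0.01$ the $w/n$ term *dominates* $\sigma^2_B$, and omitting it made a
pilot run reject 18% of genuinely neutral traits at $\alpha = 0.05$; the
mean-square version calibrates to ~6–7% over 200 simulated neutral traits,
inside the binomial interval around 5%. The within-trait additive variance
is drawn as $\hat\sigma^2_a \chi^2_\nu/\nu$ with Satterthwaite
$\nu = 2(\hat\sigma^2_a/\mathrm{SE})^2$ from the REML fit. The p-value is
one-sided toward divergent selection with add-one smoothing; a two-sided
variant exists but is off by default.

What "a neutral trait" means in the calibration suite: unstructured
breeding values plus an among-cluster variance drawn from the neutral
marker F_ST distribution. Drawing breeding values from the *structured*
marker GRM **and** planting an F-derived cluster variance would count
neutral divergence twice (a pilot showed exactly that inflation).
`sim_phenotypes(..., scale_exact = FALSE)` lets the realized among-cluster
variance fluctuate chi-square-like, as it would for a real neutral trait;
the default `scale_exact = TRUE` pins it exactly and is the right choice
for parameter-recovery studies, where "truth" must be sharp even with only
4 clusters.

## The F_ST outlier machinery

Per-locus differentiation uses the Weir–Cockerham (1984) estimator
(`weir_cockerham_fst()`), computed from per-population sample sizes, allele
frequencies and observed heterozygosities; the multi-locus value is the
ratio of summed components. One estimator serves observed and simulated
panels alike — that consistency, more than the choice of estimator, is what
makes an envelope comparison valid.

The neutral null (`island_null_simulate()`) is a structured coalescent
under a symmetric island model with infinite-alleles mutation, written in
C++. Under infinite alleles a leaf's allele is decided by the first
mutation on its path to the root, so a lineage can be *killed* at its first
mutation after assigning a fresh allele to its subtended leaves — no
genealogy is ever stored, and the state is just a set of lineages with
per-deme leaf counts. Low target F_ST means high migration
($M = 4Nm \approx 100$ for $F_{ST} \approx 0.01$), so the event loop is
migration-dominated; a local xoshiro256+ generator (seeded from R's RNG, so
`set.seed()` still governs everything) keeps per-event cost low. Migration
is first set from $F = 1/(1+M)$ and corrected by pilot runs until the
realized multi-locus F_ST is within 5% of target. Per-locus mutation rates
are drawn log-uniformly in $[0.05, 5]/D$ for $D$ demes — pairwise
coalescence times scale with $D$, so this window keeps the collapsed
biallelic heterozygosity spread over the observed range for any island
size. Alleles are collapsed to biallelic (most frequent vs rest), loci with
pooled $H_E < 0.02$ discarded as array-like ascertainment, and genes
randomly paired into diploids within demes (Hardy–Weinberg) before scoring.

The envelope (`conditional_envelope()`) partitions simulated pairs into 20
equal-count H_E bins and takes empirical 0.5%/99.5% F_ST quantiles per bin,
linearly interpolated between bin medians and flat beyond. Two honest
caveats. First, binned empirical quantiles are noisy estimators: in-sample
the envelope excludes 1% by construction, but a *fresh* draw from the same
process falls outside it ~1.2–1.4% of the time at feasible simulation
counts; tests therefore check the out-of-sample exceedance lies in
(0.5%, 2%) rather than testing a point null of exactly 1%. Second,
`detect_outliers()` re-simulates at each trimming round (flag loci outside
the envelope, recompute the multi-locus mean over unflagged loci, repeat
until the flag set stabilizes, 5 rounds maximum), and loci near a bound can
flicker between rounds because each round's envelope is itself an estimate;
a non-stable set after 5 rounds returns the last iteration with a warning.

The hotspot test is a chi-square goodness-of-fit of per-chromosome outlier
counts against uniformity (df = chromosomes − 1), plus a randomization
rule: scatter the same total uniformly 1000 times, record each replicate's
maximum per-chromosome count, and call a chromosome a hotspot when its
observed count reaches the maximum seen across all replicates. The
expectation is uniform per chromosome, not SNP-density-weighted (a weighted
variant would be a one-line change to the expected vector but is not the
default).

## Spatial structure

Coordinates are projected with an azimuthal equidistant chart about the
sample centroid — one well-defined plane, no UTM zone seams, distances
faithful at a sampling scale of ~1000 km (the meridian-arc test pins the
projection to 1% of 111.2 km/degree). One genotype represents each unique
(lat, lon); the choice is uniform and seed-deterministic.

The connection network is K-nearest-neighbours (default K = 10) with
ties broken by node order and adjacency symmetrized by union, or a distance
band (lo, hi]. Moran's I uses the binary adjacency
($I = (n/S_0)\,z'Wz/z'z$), expectation $-1/(n-1)$, and a one-sided
permutation p-value; the lag profile rebuilds 200-km bands and skips empty
ones. The double-loop evaluation of I is an oracle in the test suite.

sPCA eigendecomposes $(1/2n)\,X'(W+W')X$ for column-centered dosages $X$
and row-standardized weights $W$; each eigenvalue equals
var(score) × Moran's I(score) (up to $S_0/n$, exactly 1 without isolated
nodes), so large positive values flag global clines
(isolation-by-distance) and large negative values discrete local clusters.
Computation runs in the dual: nonzero eigenvalues of $X'HX$ equal those of
$D\,U'HU\,D$ from one SVD of $X$, so the permutation tests (re-assign
genotype rows to nodes; compare the sum of positive, respectively
|negative|, eigenvalues to the permutation distribution) cost one small
symmetric eigenproblem per permutation. These permutation tests replace the
spectral-decomposition tests of the classical implementation, whose exact
construction is not published; their calibration is demonstrated by
simulation instead (null rejection ~5%, stepping-stone landscapes give a
significant global and non-significant local test in ≥ 90% of seeds).

SPA-style cline scores fit, per locus, allele presence on standardized
predictors by binomial logistic regression (each diploid contributing two
allele draws); the score is the slope-vector norm, capped at 25 with a flag
under separation, and flags are drawn at the 95th/99th score percentiles.
Slopes are also returned in the predictors' original units, so a cline
generated at 2 per 1000 km is recovered as ≈ 2 when coordinates are
supplied in Mm. Scores are invariant to allele relabeling (the slope flips
sign, not norm). For "unsupervised" runs without trusted coordinates, the
leading genotype PCs can be supplied as latent spatial surrogates — a
documented surrogate, not an equivalent.

## Climate clustering and association

`kmedoids_ch()` standardizes the climate variables, runs PAM (build + swap)
for each candidate K, and picks K by a Calinski–Harabasz index computed
with the *medoids* as centers — a deliberately PAM-flavored CH, consistent
with the clustering it evaluates. Standardization makes the result
invariant to affine rescaling of any variable.

`sam_scan()` fits univariate logistic regressions of allele presence on
each environmental variable and requires all three of likelihood-ratio,
Wald and score (Lagrange-multiplier) tests to clear the Bonferroni
threshold $\alpha/(\text{alleles} \times \text{variables})$ — for 242
alleles and 3 variables, 0.05/726 = 6.887052e-5. The classical tool's "two
Wald tests" are not further identified in its documentation; Wald + score
alongside the LR test keeps three asymptotically equivalent statistics with
identical all-must-pass semantics. Under separation the Wald p is set
missing and the decision falls to LR + score. By default each individual
carries its subpopulation's mean environment (the climate-cluster usage);
per-individual mode exists. Cluster-level regressions use the
variance-stabilizing $\arcsin\sqrt{f}$ transform (defined, and flagged, at
the 0/1 boundary).

## The synthetic-data generators

The generators encode the study design so every stage is testable with
known truth; their defaults are the conditions everything else assumes.

* **Island model** (`sim_island_genotypes()`): Balding–Nichols deme
  frequencies — ancestral $p \sim U(0.05, 0.95)$ (bounded away from 0/1 so
  MAF filtering does not empty simulated panels), deme frequencies
  Beta-distributed with the target F_ST, genotypes binomial. Chosen over an
  explicit coalescent here because the closed-form F_ST target makes
  calibration tests sharp and fast. `target_fst = 0` short-circuits the
  Beta draw to a panmictic pool. Note that a *per-locus* draw at, say,
  F = 0.5 has enormous spread (it can even be monomorphic); loci with a
  guaranteed realized F_ST must be constructed from fixed, well-separated
  deme frequencies, which is how the planted-outlier tests do it.
* **Isolation by distance** (`sim_ibd_genotypes()`): individuals placed
  uniformly on the landscape; per-locus allele frequencies follow a
  Gaussian field with exponential correlation $\exp(-d/\sigma)$ and
  marginal variance $F\,p(1-p)$. As $\sigma \to \infty$ the field collapses
  to a single shared draw and spatial structure vanishes — the
  no-structure limiting case used in tests.
* **Climate** (`sim_climate()`): four spatial zones (k-means partition of
  the coordinates, labels ordered along the landscape diagonal), MAT means
  9/7/5/3 °C (sd 0.6), NFFD = 60 + 18·MAT + noise (so MAT and NFFD are
  positively correlated by construction), MAP means 2200/1500/1000/600 mm
  (sd 120, floored at 0). The within-zone spreads are free choices — the
  source design reports only that its four climate classes were
  well-separated with balanced sizes — set so that between-zone separation
  is several within-zone standard deviations, i.e. zones a clustering
  method *should* recover (ARI ≥ 0.9 is then a meaningful bar for the
  method, not for the data).
* **Clinal loci** (`sim_clinal_loci()`): selected loci are overwritten with
  $\text{logistic}(\alpha + s z)$ frequencies in a supplied predictor;
  the generator's slope is in the predictor's units, so cline-score recovery can be checked in those units.
* **Phenotypes** (`sim_phenotypes()`): breeding values through the
  Cholesky factor of a supplied relationship matrix; cluster effects with
  variance $2\sigma^2_a Q_{ST}/(1-Q_{ST})$; i.i.d. ramet residuals; clonal
  ramets share genotype and breeding value. One RNG stream per generator,
  derived from the configuration seed by a fixed splitting rule, so
  modules can be re-run and tested independently.

## Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to make each property
measurable while keeping the whole suite fast to re-run: parameter recovery
at 400 genotypes × 5000 loci × 3 ramets over 10 seeds per condition;
neutrality calibration over 200 simulated traits on a 200-genotype,
1500-locus panel; the island-model null at 20 demes (the default stays at
100, matching classical Fdist practice), 10,000–20,000 simulated loci per
envelope and a 2000-locus calibration pilot; sPCA permutation tests at
99–199 permutations. Tolerances: REML convergence 1e-8 (relative restricted
log-likelihood), oracle agreement 1e-6, GRM ridge 1e-6 × mean diagonal
applied only when the smallest eigenvalue is negative and always recorded.
Ties in KNN break by node order; quantiles are R's default type 7;
permutation p-values use the add-one convention throughout.

## Limitations

The generators emulate drift, isolation by distance, climate-driven clines,
additive architecture and clonal replication. They do not emulate linkage
disequilibrium among neutral loci (loci are independent given the deme
frequencies), array ascertainment beyond an H_E floor and MAF bounds,
genotyping error or informative missingness, non-additive genetic variance,
unbalanced ramet designs, or selection acting through time. Passing tests
therefore establish that each method recovers what it targets under its own
model assumptions at realistic sizes — not that those assumptions hold for
any particular real data set. The P_ST assembly, the χ²/Satterthwaite
neutrality null, and the permutation replacements for the classical sPCA
tests are documented approximations; where a published reference
construction exists only as an unpublished implementation detail, this
package prefers a transparent, testable construction and says so.
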