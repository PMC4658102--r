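#' Simulation configuration
#'
#' Encodes the study design the pipeline assumes: a handful of
#' climate-defined subpopulations with low marker differentiation, clonally
#' replicated common-garden phenotypes with an additive architecture, a few
#' clinal loci, and an isolation-by-distance landscape. Defaults mirror that
#' design: 4 subpopulations of 100 genotypes, 5000 loci, target multi-locus
#' F_ST of 0.01, narrow-sense heritability 0.5 and Q_ST 0.2, 3 clonal ramets
#' per genotype on a 1000 x 1000 km landscape with a 50 km dispersal scale.
#'
#' @param n_pops number of subpopulations (demes).
#' @param n_per_pop genotypes sampled per subpopulation.
#' @param n_loci number of biallelic loci.
#' @param target_fst target multi-locus Weir-Cockerham F_ST in \[0, 1).
#' @param n_clinal_loci number of loci overwritten with a climate cline.
#' @param cline_slope logistic slope of clinal allele frequencies per unit of
#'   the cline predictor (per 1000 km when the predictor is a coordinate
#'   expressed in Mm; per standardized unit for climate predictors).
#' @param h2_true planted narrow-sense heritability in \[0, 1\].
#' @param qst_true planted Q_ST in \[0, 1).
#' @param n_ramets clonal ramets measured per genotype (>= 1).
#' @param landscape_extent side of the square landscape, km.
#' @param dispersal_sigma spatial correlation scale of deme allele
#'   frequencies, km.
#' @param seed integer seed; every generator derives its own stream from it.
#'
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_pops = 4L, n_per_pop = 100L, n_loci = 5000L,
                       target_fst = 0.01, n_clinal_loci = 10L,
                       cline_slope = 2, h2_true = 0.5, qst_true = 0.2,
                       n_ramets = 3L, landscape_extent = 1000,
                       dispersal_sigma = 50, seed = 1L) {
  cfg <- list(n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
              n_loci = as.integer(n_loci), target_fst = target_fst,
              n_clinal_loci = as.integer(n_clinal_loci),
              cline_slope = cline_slope, h2_true = h2_true,
              qst_true = qst_true, n_ramets = as.integer(n_ramets),
              landscape_extent = landscape_extent,
              dispersal_sigma = dispersal_sigma, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_pops >= 1, n_per_pop >= 1, n_loci >= 1, n_ramets >= 1,
              target_fst >= 0, target_fst < 1,
              h2_true >= 0, h2_true <= 1,
              qst_true >= 0, qst_true < 1,
              n_clinal_loci >= 0, landscape_extent > 0, dispersal_sigma > 0)
  })
  class(cfg) <- "sim_config"
  cfg
}
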