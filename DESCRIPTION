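Package: qstfst
Title: Quantitative-Genetic and Landscape-Genomic Tests of Local Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated inference chain for detecting local adaptation in
    structured plant populations from SNP genotypes, clonally replicated
    common-garden phenotypes, geography and climate. Implements marker-based
    realized relationship matrices, REML animal-model estimation of Q_ST,
    heritability and P_ST, a simulated Q_ST-F_ST neutrality test, Fdist-style
    F_ST outlier detection with a coalescent island-model null and
    heterozygosity-conditioned envelopes, spatial autocorrelation and spatial
    PCA diagnostics of isolation-by-distance, climate-envelope clustering with
    allele-frequency-environment association scans, and multi-evidence
    integration into an adaptive-SNP report. Ships a synthetic-data generator
    with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    geosphere,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    optparse,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
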