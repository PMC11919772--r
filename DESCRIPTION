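Package: methvar
Title: Epigenome-Wide DNA Methylation Variance Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Methvar", "Developers", email = "methvar@example.org", role = c("aut", "cre"))
Description: Detection of variably methylated positions (VMPs) and differentially
    methylated positions (DMPs) in case-control DNA methylation studies. Implements
    per-cohort covariate residualisation of beta values, Levene (Brown-Forsythe),
    Bartlett and Fligner-Killeen variance tests with signed Z-scores, mean-effect
    EWAS by multiple regression, Bayesian empirical-null bias/inflation correction
    of test statistics via a three-component Gaussian mixture fitted by Gibbs
    sampling, sample-size-weighted Stouffer and inverse-variance-weighted
    (DerSimonian-Laird) meta-analysis across cohorts, Benjamini-Hochberg and
    Bonferroni multiplicity control, Stouffer-Liptak/Sidak aggregation of probes
    into variably methylated regions, Fisher-exact gene-set and genomic-feature
    enrichment, and phenome-wide epigenetic covariance against external EWAS
    catalogues. Includes a multi-cohort synthetic-data generator with planted
    variance-ratio and mean-shift effects for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    matrixStats,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
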