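# methvar

Epigenome-wide meta-analysis of DNA methylation **variance** for case-control
cohort studies.

## The problem

Classical EWAS of psychiatric and other complex disorders compare *mean*
methylation between cases and controls (differentially methylated positions,
DMPs). But disorders with strong phenotypic heterogeneity can also show
altered methylation *dispersion*: CpG sites where cases are more (or less)
variable than controls — variably methylated positions (VMPs) — which mean
tests cannot see. `methvar` implements the full multi-cohort VMP/DMP
pipeline for array-style beta-value matrices:

1. **QC** — sample filters (detection P > 0.01 in > 10% of probes; median
   methylated/unmethylated intensity < 2500; reported-vs-predicted sex
   mismatch) and probe filters (detection rule; non-autosomal, non-CpG,
   cross-hybridising and SNP-proximal blacklists), plus cohort demographics
   (continuity-corrected 2×2 χ², Welch *t* on epigenetic age).
2. **Per-cohort association** — beta values residualised on sentrix
   ID/position, age, sex, smoking score and cell proportions; then per probe:
   Levene (Brown–Forsythe), Bartlett and Fligner–Killeen variance tests with
   signed Z-scores (positive = greater dispersion in cases), and a
   mean-effect EWAS (β = case − control methylation difference, SE, *P*,
   Z = β/SE).
3. **Empirical-null correction** — a three-component Gaussian mixture
   p₀N(μ₀,σ₀²) + p₁N(μ₁,σ₁²) + p₂N(μ₂,σ₂²) fitted to the signed Z-scores by
   Gibbs sampling; the central component's mean (bias) and SD (inflation)
   rescale the statistics, z′ = (z − bias)/inflation, without letting true
   signal inflate the null (unlike genomic-control λ).
4. **Meta-analysis** — variance: Stouffer's method weighted by √n per
   cohort, Z_meta = Σ√nᵢzᵢ/√Σnᵢ, on probes present in ≥ 2 cohorts; mean:
   inverse-variance-weighted fixed and DerSimonian–Laird random effects with
   τ², Q, I². BH FDR < 0.05 defines VMPs/DMPs; α/m is the epigenome-wide
   (Bonferroni) line.
5. **Regions** — comb-p-style aggregation: seed/extend on *P* thresholds,
   Stouffer–Liptak combination under a distance-binned Z autocorrelation,
   Šidák correction 1 − (1 − p)^(total span / region span), reported at
   n_probes ≥ 2 and P_Šidák < 0.05.
6. **Downstream** — Fisher-exact enrichment of VMP genes/probes in tissue,
   disorder and genomic-feature sets (direction-stratified), and
   phenome-wide epigenetic covariance: Pearson *r* between meta-analysis
   Z-scores and standardised external-catalogue effect sizes (traits with
   ≥ 10 shared probes).

A first-class synthetic-data module generates multi-cohort studies from a
latent-logistic model with planted variance ratios (ρ) and latent mean
shifts (Δ), covariate/batch structure and matching annotation, so every
stage is testable against known ground truth.

## Worked example

```r
library(methvar)

cfg <- sim_config(n_cohorts = 3, n_cases = 400, n_controls = 400,
                  n_probes = 20000, variance_ratio = 2, seed = 2024)
cohorts <- lapply(1:3, function(i) generate_cohort(cfg, i))
res <- run_pipeline(cohorts, adjust = TRUE, seed = 2024)
print(res)
#> methvar pipeline result: 3 cohorts, 20000 probes meta-analysed
#> VMP: 103  DMP: 85  both: 9 (FDR < 0.05)
score_recovery(res$meta, cohorts[[1]]$truth, "variance")
#> $sensitivity
#> [1] 1
#> $fdp
#> [1] 0.1071429
#> $n_flagged
#> [1] 112
#> $n_planted
#> [1] 100
```

All 100 planted variance effects are recovered at FDR < 0.05. Of the 112
variance discoveries, 7 are BH-admitted nulls and 5 are planted
*mean-shift* probes — on bounded beta values a latent mean shift also
changes the variance through the logistic map, so the planted classes
overlap slightly on the analysis scale ("both" = 9 of 197 significant
sites), mirroring the small but nonzero VMP/DMP overlap seen in real
cohort data.

Demographics helpers work straight from printed summary tables:

```r
chisq_2x2(matrix(c(203, 230, 227, 123), 2, byrow = TRUE))$statistic
#> [1] 24.53777
welch_t(46.61, 8.33, 433, 41.89, 7.45, 350)$mean_diff
#> [1] 4.72
```

## Command line

```sh
Rscript -e 'methvar::methvar_cli()' simulate --seed 1 --probes 20000 --out sim/
Rscript -e 'methvar::methvar_cli()' all --seed 1 --out results/
```

Subcommands: `simulate`, `qc`, `ewas`, `adjust`, `meta`, `regions`,
`covary`, `all`.
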