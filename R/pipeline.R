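#' Run the full variance/mean EWAS meta-analysis pipeline
#'
#' Orchestrates, per cohort: sample and probe QC, covariate residualisation,
#' the three variance tests and the mean-effect EWAS, empirical-null
#' bias/inflation adjustment of the variance Z-scores and of the mean
#' effect/SE pairs; then across cohorts: sample-size-weighted Stouffer and
#' IVW random-effects meta-analysis on the probes present in at least two
#' cohorts, BH/Bonferroni multiplicity control, VMP/DMP classification and
#' (optionally) region aggregation. Strata rerun the same pipeline on a
#' sample subset (e.g. male-only), not new code.
#'
#' @param cohorts List of cohort objects, each a list with `beta`,
#'   `samplesheet` and optionally `detp`, `intensity` (e.g. from
#'   [generate_cohort()]).
#' @param annotation Probe annotation (for probe QC and regions); optional.
#' @param covariates Covariate columns for the design.
#' @param z_col Variance test whose Z-scores are meta-analysed
#'   (default `levene_z`).
#' @param adjust Apply the empirical-null adjustment per cohort (default
#'   TRUE; disable for speed in calibration studies).
#' @param regions Call variably methylated regions from the variance
#'   meta-analysis (requires `annotation`).
#' @param stratum Optional logical function of a samplesheet row subset,
#'   e.g. `function(ss) ss$predicted_sex == "male"`.
#' @param seed Seed for the empirical-null Gibbs fits.
#' @param alpha FDR level for VMP/DMP definitions.
#' @param niter,burnin Gibbs settings passed to [fit_empirical_null()].
#' @return list of class `methvar_result`: `cohort_stats`, `null_estimates`,
#'   `meta`, `classification`, `regions`, and a `manifest` of per-stage
#'   counts and settings.
#' @export
run_pipeline <- function(cohorts, annotation = NULL,
                         covariates = c("horvath_age", "predicted_sex",
                                        "smoking_score", "sentrix_id",
                                        "sentrix_position"),
                         z_col = "levene_z", adjust = TRUE, regions = FALSE,
                         stratum = NULL, seed = 1L, alpha = 0.05,
                         niter = 5000L, burnin = 2000L) {
  stopifnot(length(cohorts) >= 2L)
  manifest <- list(seed = seed, alpha = alpha, z_col = z_col,
                   n_cohorts = length(cohorts), stages = list())
  stats_list <- list()
  null_estimates <- list()
  n_by_cohort <- numeric(length(cohorts))
  for (ci in seq_along(cohorts)) {
    co <- cohorts[[ci]]
    ss <- co$samplesheet
    if (!is.null(stratum)) {
      keep <- stratum(ss)
      ss <- ss[keep, , drop = FALSE]
      co$beta <- co$beta[, ss$sample_id, drop = FALSE]
      if (!is.null(co$detp)) co$detp <- co$detp[, ss$sample_id, drop = FALSE]
    }
    fs <- suppressWarnings(
      filter_samples(co$beta, co$detp, co$intensity, ss))
    ss <- ss[ss$sample_id %in% fs$kept, , drop = FALSE]
    beta <- co$beta[, fs$kept, drop = FALSE]
    if (!is.null(annotation)) {
      fp <- filter_probes(beta, co$detp, annotation)
      beta <- beta[fp$kept, , drop = FALSE]
    } else fp <- NULL
    st <- run_cohort_association(beta, ss, covariates)
    ne <- NULL
    if (adjust) {
      z_cols <- intersect(c("levene_z", "bartlett_z", "fligner_z"), names(st))
      ne <- list()
      for (zc in z_cols) {
        ok <- is.finite(st[[zc]])
        fit <- fit_empirical_null(st[[zc]][ok], niter = niter, burnin = burnin,
                                  seed = seed + 131L * ci)
        adj <- adjust_z(st[[zc]][ok], fit)
        st[[zc]][ok] <- adj$z
        st[[sub("_z$", "_p", zc)]][ok] <- adj$p.value
        ne[[zc]] <- fit
      }
      ok <- is.finite(st$beta) & is.finite(st$se) & st$se > 0
      fit_m <- fit_empirical_null((st$beta / st$se)[ok], niter = niter,
                                  burnin = burnin, seed = seed + 131L * ci + 7L)
      adj <- adjust_effects(st$beta[ok], st$se[ok], fit_m)
      st$beta[ok] <- adj$beta; st$se[ok] <- adj$se
      st$z_mean[ok] <- adj$z; st$p_mean[ok] <- adj$p.value
      ne$mean <- fit_m
    }
    stats_list[[ci]] <- st
    null_estimates[[ci]] <- ne
    n_by_cohort[ci] <- attr(st, "n_total")
    manifest$stages[[ci]] <- list(
      cohort = ci,
      samples_in = nrow(co$samplesheet), samples_kept = length(fs$kept),
      probes_in = nrow(co$beta),
      probes_kept = if (is.null(fp)) nrow(co$beta) else length(fp$kept))
  }
  meta <- run_meta(stats_list, n_by_cohort, z_col = z_col, alpha = alpha)
  mean_tab <- data.frame(probe_id = meta$probe_id, q = meta$q_mean)
  cls <- classify_sites(
    data.frame(probe_id = meta$probe_id, z_meta = meta$z_meta, q = meta$q),
    mean_tab, alpha = alpha)
  reg <- NULL
  if (regions) {
    if (is.null(annotation)) stop("region calling requires an annotation")
    reg <- find_regions(meta, annotation)
  }
  manifest$n_probes_meta <- nrow(meta)
  manifest$m_variance <- attr(meta, "m_variance")
  manifest$n_by_cohort <- n_by_cohort
  out <- list(cohort_stats = stats_list, null_estimates = null_estimates,
              meta = meta, classification = cls, regions = reg,
              manifest = manifest)
  class(out) <- "methvar_result"
  out
}

#' Score recovery of planted effects against simulation ground truth
#'
#' Confusion-matrix style recount: sensitivity is the fraction of planted
#' variance (or mean) effects flagged significant, and the empirical false
#' discovery proportion the fraction of flagged probes with no planted effect
#' of that type.
#'
#' @param meta A [run_meta()] table (or the `meta` element of
#'   [run_pipeline()]).
#' @param truth GroundTruth data.frame from [generate_cohort()].
#' @param what "variance" or "mean".
#' @return list(sensitivity, fdp, n_flagged, n_planted).
#' @export
score_recovery <- function(meta, truth, what = c("variance", "mean")) {
  what <- match.arg(what)
  tr <- truth[match(meta$probe_id, truth$probe_id), ]
  planted <- if (what == "variance")
    tr$effect_class %in% c("variance_up", "variance_down")
  else tr$effect_class == "mean_shift"
  flag <- if (what == "variance") meta$fdr_significant else meta$fdr_significant_mean
  flag <- !is.na(flag) & flag
  list(sensitivity = if (sum(planted)) sum(flag & planted) / sum(planted) else NA_real_,
       fdp = if (sum(flag)) sum(flag & !planted) / sum(flag) else 0,
       n_flagged = sum(flag), n_planted = sum(planted))
}

#' @export
print.methvar_result <- function(x, ...) {
  cat(sprintf("methvar pipeline result: %d cohorts, %d probes meta-analysed\n",
              x$manifest$n_cohorts, x$manifest$n_probes_meta))
  cat(sprintf("VMP: %d  DMP: %d  both: %d (FDR < %.2f)\n",
              x$classification$counts["VMP"], x$classification$counts["DMP"],
              x$classification$counts["both"], x$manifest$alpha))
  if (!is.null(x$regions))
    cat(sprintf("regions: %d with P_Sidak < 0.05\n", nrow(x$regions)))
  invisible(x)
}
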