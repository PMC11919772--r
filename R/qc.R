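#' Continuity-corrected chi-squared test for an r x c contingency table
#'
#' For 2x2 tables the Yates-style correction shrinks each |O - E| by
#' min(0.5, |O - E|) before squaring; this is the form that reproduces the
#' sex-by-diagnosis statistics printed for all five cohorts analysed here
#' (24.538, 4.508, 3.845, 2.838, 0.052). Correction is applied only to 2x2
#' tables, as in standard practice.
#'
#' @param tab Integer matrix of counts (groups x categories).
#' @param correct Apply the continuity correction (2x2 only).
#' @return list(statistic, df, p.value).
#' @export
chisq_2x2 <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) stop("counts must be nonnegative and finite")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  d <- abs(tab - E)
  if (correct && all(dim(tab) == c(2L, 2L))) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom, computable
#' from printed group means/SDs/sizes.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return list(statistic, df, p.value, mean_diff) with mean_diff = m1 - m2.
#' @export
welch_t <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (m1 - m2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df,
       p.value = 2 * stats::pt(-abs(t), df), mean_diff = m1 - m2)
}

reasons_to_string <- function(lst) {
  vapply(lst, function(r) if (length(r)) paste(r, collapse = ";") else "", "")
}

#' Sample-level quality-control filter
#'
#' Removes samples that (1) have detection P > 0.01 at more than 10% of
#' probes, (2) have median methylated and/or unmethylated signal intensity
#' below 2500 units, or (3) show a reported-vs-predicted sex mismatch or
#' undefined predicted sex. Samples with missing reported sex but conclusive
#' predicted sex are retained. The intensity and sex rules are soft-skipped
#' with a warning when their inputs are absent, so the pipeline stays runnable
#' on minimal synthetic inputs.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param detp Probe-by-sample detection P matrix (optional).
#' @param intensity data.frame(sample_id, median_methylated,
#'   median_unmethylated), optional.
#' @param samplesheet Sample sheet; `predicted_sex` and optional
#'   `reported_sex` drive the sex rule.
#' @param detp_threshold,detp_sample_fraction,intensity_min Filter settings.
#' @return list(kept = character vector of sample IDs, report = `qc_report`).
#' @export
filter_samples <- function(beta, detp = NULL, intensity = NULL, samplesheet,
                           detp_threshold = 0.01, detp_sample_fraction = 0.10,
                           intensity_min = 2500) {
  if (ncol(beta) == 0L) stop("empty beta matrix")
  ids <- colnames(beta)
  if (!setequal(ids, samplesheet$sample_id))
    stop("sample IDs of beta matrix and sample sheet are misaligned")
  samplesheet <- samplesheet[match(ids, samplesheet$sample_id), , drop = FALSE]
  reasons <- rep(list(character(0)), length(ids))

  det_frac <- rep(NA_real_, length(ids))
  if (!is.null(detp)) {
    if (!identical(colnames(detp), ids)) detp <- detp[, ids, drop = FALSE]
    det_frac <- colMeans(detp > detp_threshold)
    bad <- det_frac > detp_sample_fraction
    for (i in which(bad)) reasons[[i]] <- c(reasons[[i]], "detection")
  }

  med_m <- med_u <- rep(NA_real_, length(ids))
  if (!is.null(intensity)) {
    m <- match(ids, intensity$sample_id)
    med_m <- intensity$median_methylated[m]
    med_u <- intensity$median_unmethylated[m]
    bad <- !is.na(med_m) & !is.na(med_u) & (med_m < intensity_min | med_u < intensity_min)
    for (i in which(bad)) reasons[[i]] <- c(reasons[[i]], "intensity")
  } else {
    warning("no intensity summary supplied; intensity filter skipped")
  }

  if (!is.null(samplesheet$predicted_sex)) {
    pred <- samplesheet$predicted_sex
    rep_sex <- if (is.null(samplesheet$reported_sex)) rep(NA_character_, length(ids))
               else samplesheet$reported_sex
    undef <- is.na(pred) | !(pred %in% c("male", "female"))
    mismatch <- !undef & !is.na(rep_sex) & rep_sex != pred
    for (i in which(undef)) reasons[[i]] <- c(reasons[[i]], "undefined predicted sex")
    for (i in which(mismatch)) reasons[[i]] <- c(reasons[[i]], "sex mismatch")
  } else {
    warning("no predicted_sex column; sex-mismatch filter skipped")
  }

  kept <- lengths(reasons) == 0L
  report <- list(
    samples = data.frame(sample_id = ids, detection_fraction = det_frac,
                         median_methylated = med_m, median_unmethylated = med_u,
                         kept = kept, reasons = reasons_to_string(reasons),
                         stringsAsFactors = FALSE),
    n_input = length(ids), n_kept = sum(kept), n_removed = sum(!kept))
  class(report) <- "qc_report"
  list(kept = ids[kept], report = report)
}

#' Probe-level quality-control filter
#'
#' Removes probes with detection P > 0.01 in more than 10% of samples and
#' probes carrying any blacklist flag in the annotation (non-autosomal,
#' non-CpG, cross-hybridising, SNP within 5 nt). Blacklist membership is an
#' annotation fact, not computed here.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param detp Detection P matrix (optional; detection rule skipped if NULL).
#' @param annotation Probe annotation covering every probe, with logical
#'   `flag_*` columns.
#' @inheritParams filter_samples
#' @return list(kept = character vector of probe IDs, report = `qc_report`).
#' @export
filter_probes <- function(beta, detp = NULL, annotation,
                          detp_threshold = 0.01, detp_probe_fraction = 0.10) {
  if (nrow(beta) == 0L) stop("empty beta matrix")
  ids <- rownames(beta)
  missing <- setdiff(ids, annotation$probe_id)
  if (length(missing))
    stop("probes missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  ann <- annotation[match(ids, annotation$probe_id), , drop = FALSE]
  reasons <- rep(list(character(0)), length(ids))

  det_frac <- rep(NA_real_, length(ids))
  if (!is.null(detp)) {
    det_frac <- rowMeans(detp[ids, , drop = FALSE] > detp_threshold)
    for (i in which(det_frac > detp_probe_fraction))
      reasons[[i]] <- c(reasons[[i]], "detection")
  }
  flag_cols <- grep("^flag_", names(ann), value = TRUE)
  for (fc in flag_cols) {
    hit <- which(isTRUE_vec(ann[[fc]]))
    for (i in hit) reasons[[i]] <- c(reasons[[i]], sub("^flag_", "", fc))
  }
  kept <- lengths(reasons) == 0L
  report <- list(
    probes = data.frame(probe_id = ids, detection_fraction = det_frac,
                        kept = kept, reasons = reasons_to_string(reasons),
                        stringsAsFactors = FALSE),
    n_input = length(ids), n_kept = sum(kept), n_removed = sum(!kept))
  class(report) <- "qc_report"
  list(kept = ids[kept], report = report)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.qc_report <- function(x, ...) {
  what <- if (!is.null(x$samples)) "samples" else "probes"
  cat(sprintf("QC report: %d %s in, %d kept, %d removed\n",
              x$n_input, what, x$n_kept, x$n_removed))
  tab <- table(unlist(strsplit(x[[what]]$reasons[!x[[what]]$kept], ";")))
  if (length(tab)) {
    cat("removal reasons:\n")
    for (r in names(tab)) cat(sprintf("  %-24s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Cohort demographic summary (sex balance and epigenetic age)
#'
#' Reproduces the standard cohort-demographics comparisons: a 2x2
#' sex-by-diagnosis chi-squared test with continuity correction and a Welch
#' (unequal-variance) two-sample t-test on Horvath epigenetic age.
#' Conventions follow the printed table they emulate: `mean_diff` is
#' case - control, while the t-statistic is computed as control vs case.
#'
#' @param samplesheet Sample sheet with `diagnosis` (control/case),
#'   `predicted_sex` and `horvath_age` columns.
#' @return list of class `demographics_summary`.
#' @export
summarize_cohort <- function(samplesheet) {
  stopifnot(all(c("diagnosis", "predicted_sex", "horvath_age") %in% names(samplesheet)))
  g <- factor(samplesheet$diagnosis, levels = c("control", "case"))
  if (any(table(g) < 2L)) stop("each diagnosis group needs at least 2 samples")
  sex <- factor(samplesheet$predicted_sex, levels = c("male", "female"))
  tab <- table(g, sex)
  chi <- chisq_2x2(unclass(tab))
  age <- split(samplesheet$horvath_age, g)
  st <- vapply(age, function(a) c(mean(a), stats::sd(a), length(a)), numeric(3))
  tt <- welch_t(st[1, "control"], st[2, "control"], st[3, "control"],
                st[1, "case"], st[2, "case"], st[3, "case"])
  out <- list(
    n_controls = sum(g == "control"), n_cases = sum(g == "case"),
    sex_counts = tab,
    chisq_statistic = chi$statistic, chisq_df = chi$df, chisq_p = chi$p.value,
    age_mean = st[1, ], age_sd = st[2, ],
    mean_diff = st[1, "case"] - st[1, "control"],
    t_statistic = tt$statistic, t_df = tt$df, t_p = tt$p.value)
  class(out) <- "demographics_summary"
  out
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat(sprintf("n = %d controls / %d cases\n", x$n_controls, x$n_cases))
  cat(sprintf("sex chi-squared = %.3f (df = %d, P = %.3g)\n",
              x$chisq_statistic, x$chisq_df, x$chisq_p))
  cat(sprintf("Horvath age: controls %.2f (%.2f), cases %.2f (%.2f); diff (case-control) %.2f\n",
              x$age_mean["control"], x$age_sd["control"],
              x$age_mean["case"], x$age_sd["case"], x$mean_diff))
  cat(sprintf("Welch t = %.3f (df = %.1f, P = %.3g)\n", x$t_statistic, x$t_df, x$t_p))
  invisible(x)
}
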