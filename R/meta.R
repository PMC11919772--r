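#' Sample-size-weighted Stouffer meta-analysis of signed Z-scores
#'
#' Combines per-cohort signed Z-scores with weights equal to the square root
#' of each cohort's analysed sample size:
#' \deqn{Z_{meta} = \sum_i \sqrt{n_i} z_i / \sqrt{\sum_i n_i}}
#' Probes contributing fewer than two non-missing cohorts are excluded (NA
#' row, counted in the `n_excluded` attribute), never an error.
#'
#' @param z Probe-by-cohort matrix of signed Z-scores (NA = probe absent from
#'   that cohort), or a numeric vector for a single probe.
#' @param n Cohort-level analysed sample sizes (length = number of cohorts).
#' @return data.frame(z_meta, p_meta, n_studies) with attribute `n_excluded`.
#' @export
stouffer_meta <- function(z, n) {
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  stopifnot(ncol(z) == length(n), all(n > 0))
  contrib <- !is.na(z)
  n_studies <- rowSums(contrib)
  w <- sqrt(n)
  num <- rowSums(sweep(z, 2, w, `*`), na.rm = TRUE)
  den <- sqrt(rowSums(sweep(contrib, 2, n, `*`)))
  zm <- num / den
  zm[n_studies < 2L] <- NA_real_
  out <- data.frame(z_meta = zm, p_meta = 2 * stats::pnorm(-abs(zm)),
                    n_studies = n_studies)
  attr(out, "n_excluded") <- sum(n_studies < 2L)
  out
}

#' Inverse-variance-weighted fixed/random effects meta-analysis
#'
#' Fixed effect: weights 1/se^2. Between-study variance by DerSimonian-Laird:
#' tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w)); random-effect
#' weights 1/(se^2 + tau^2). Heterogeneity is summarised by Cochran's Q and
#' I^2 = max(0, (Q - (k-1))/Q). Probes with fewer than two contributing
#' cohorts are returned as NA rows.
#'
#' @param b,se Probe-by-cohort matrices (or vectors for a single probe) of
#'   effect sizes and standard errors; NA marks a missing cohort.
#' @return data.frame with beta_fe, se_fe, p_fe, beta_re, se_re, p_re, tau2,
#'   Q, I2, n_studies.
#' @export
ivw_meta <- function(b, se) {
  if (is.vector(b)) { b <- matrix(b, nrow = 1); se <- matrix(se, nrow = 1) }
  stopifnot(identical(dim(b), dim(se)))
  if (any(se <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  contrib <- !is.na(b) & !is.na(se)
  k <- rowSums(contrib)
  w <- 1 / se^2
  w[!contrib] <- NA
  sw <- rowSums(w, na.rm = TRUE)
  swb <- rowSums(w * b, na.rm = TRUE)
  beta_fe <- swb / sw
  se_fe <- 1 / sqrt(sw)
  Q <- rowSums(w * (b - beta_fe)^2, na.rm = TRUE)
  sw2 <- rowSums(w^2, na.rm = TRUE)
  tau2 <- pmax(0, (Q - (k - 1)) / (sw - sw2 / sw))
  wr <- 1 / sweep(se^2, 1, tau2, `+`)
  wr[!contrib] <- NA
  swr <- rowSums(wr, na.rm = TRUE)
  beta_re <- rowSums(wr * b, na.rm = TRUE) / swr
  se_re <- 1 / sqrt(swr)
  I2 <- ifelse(Q > 0, pmax(0, (Q - (k - 1)) / Q), 0)
  out <- data.frame(
    beta_fe = beta_fe, se_fe = se_fe,
    p_fe = 2 * stats::pnorm(-abs(beta_fe / se_fe)),
    beta_re = beta_re, se_re = se_re,
    p_re = 2 * stats::pnorm(-abs(beta_re / se_re)),
    tau2 = tau2, Q = Q, I2 = I2, n_studies = k)
  out[k < 2L, setdiff(names(out), "n_studies")] <- NA
  out
}

#' Multiplicity control: BH q-values and the Bonferroni threshold
#'
#' Benjamini-Hochberg step-up q-values across the m tested probes, plus the
#' Bonferroni threshold alpha/m and significance flags for both. m is the
#' number of probes entering this meta-analysis, not the array size.
#'
#' @param p Vector of P-values in (0, 1]; NAs are carried through unflagged.
#' @param alpha Significance level (default 0.05).
#' @return list(q, bonferroni_threshold, fdr_significant,
#'   bonferroni_significant, m).
#' @export
multiplicity <- function(p, alpha = 0.05) {
  if (length(p) == 0L) stop("empty P-value vector")
  m <- sum(!is.na(p))
  q <- stats::p.adjust(p, method = "BH")
  thr <- alpha / m
  list(q = q, bonferroni_threshold = thr,
       fdr_significant = !is.na(q) & q < alpha,
       bonferroni_significant = !is.na(p) & p < thr,
       m = m)
}

#' Classify probes as VMP / DMP / both / neither
#'
#' Joins the variance and mean meta-analysis tables on their shared probe
#' universe and labels each probe by which analyses reach FDR significance.
#' Also reports the fraction of VMPs with increased variance (positive
#' meta-analysis Z).
#'
#' @param meta_variance data.frame with probe_id, z_meta and q (variance).
#' @param meta_mean data.frame with probe_id and q (mean effects).
#' @param alpha FDR level for both definitions.
#' @return list(table = per-probe labels, counts, pct_vmp_up).
#' @export
classify_sites <- function(meta_variance, meta_mean, alpha = 0.05) {
  shared <- intersect(meta_variance$probe_id, meta_mean$probe_id)
  if (length(shared) == 0L) stop("variance and mean tables share no probes")
  v <- meta_variance[match(shared, meta_variance$probe_id), ]
  m <- meta_mean[match(shared, meta_mean$probe_id), ]
  vmp <- !is.na(v$q) & v$q < alpha
  dmp <- !is.na(m$q) & m$q < alpha
  label <- ifelse(vmp & dmp, "both",
                  ifelse(vmp, "VMP", ifelse(dmp, "DMP", "neither")))
  tab <- data.frame(probe_id = shared, vmp = vmp, dmp = dmp, label = label,
                    z_variance = v$z_meta, stringsAsFactors = FALSE)
  n_vmp <- sum(vmp)
  list(table = tab,
       counts = c(VMP = sum(label == "VMP"), DMP = sum(label == "DMP"),
                  both = sum(label == "both"), neither = sum(label == "neither")),
       pct_vmp_up = if (n_vmp > 0) 100 * sum(vmp & v$z_meta > 0) / n_vmp else NA_real_)
}

#' Cross-cohort meta-analysis of per-cohort association statistics
#'
#' Aligns per-cohort (adjusted) summary statistics on the union of probes
#' reported in at least two cohorts, runs the sample-size-weighted Stouffer
#' combination on the variance Z-scores and IVW fixed/random effects on the
#' mean effects, applies BH/Bonferroni multiplicity control, and builds the
#' per-cohort direction strings ("+"/"-", "?" where a cohort is missing).
#'
#' @param stats_list List of `cohort_stats`-style data.frames (one per
#'   cohort) with probe_id, a `<z_col>` column, beta and se.
#' @param n_by_cohort Analysed sample size per cohort; defaults to the
#'   `n_total` attribute of each element.
#' @param z_col Variance Z-score column to combine (default `levene_z`).
#' @param alpha FDR / Bonferroni level.
#' @return data.frame of class `meta_stats` with Stouffer, IVW, heterogeneity
#'   and multiplicity columns plus direction strings.
#' @export
run_meta <- function(stats_list, n_by_cohort = NULL, z_col = "levene_z",
                     alpha = 0.05) {
  stopifnot(length(stats_list) >= 2L)
  if (is.null(n_by_cohort))
    n_by_cohort <- vapply(stats_list, function(s) attr(s, "n_total"), 0)
  stopifnot(length(n_by_cohort) == length(stats_list), all(n_by_cohort > 0))
  probes <- sort(unique(unlist(lapply(stats_list, `[[`, "probe_id"))))
  getm <- function(col) {
    m <- vapply(stats_list, function(s) {
      v <- s[[col]][match(probes, s$probe_id)]
      if (is.null(v)) rep(NA_real_, length(probes)) else v
    }, numeric(length(probes)))
    matrix(m, nrow = length(probes))
  }
  zv <- getm(z_col)
  st <- stouffer_meta(zv, n_by_cohort)
  bm <- getm("beta"); sm <- getm("se")
  zmean <- getm("z_mean")
  iv <- ivw_meta(bm, sm)
  keep <- st$n_studies >= 2L | iv$n_studies >= 2L
  dirstr <- function(zz) apply(zz, 1, function(r)
    paste(ifelse(is.na(r), "?", ifelse(r > 0, "+", "-")), collapse = ""))
  out <- data.frame(probe_id = probes, n_studies = st$n_studies,
                    z_meta = st$z_meta, p_meta = st$p_meta,
                    direction_variance = dirstr(zv),
                    direction_mean = dirstr(zmean),
                    stringsAsFactors = FALSE)
  out <- cbind(out, iv[, c("beta_fe", "se_fe", "p_fe", "beta_re", "se_re",
                           "p_re", "tau2", "Q", "I2")])
  out <- out[keep, , drop = FALSE]
  mv <- multiplicity(out$p_meta, alpha)
  out$q <- mv$q
  out$fdr_significant <- mv$fdr_significant
  out$bonferroni_significant <- mv$bonferroni_significant
  mm <- multiplicity(out$p_re, alpha)
  out$q_mean <- mm$q
  out$fdr_significant_mean <- mm$fdr_significant
  out$bonferroni_significant_mean <- mm$bonferroni_significant
  attr(out, "m_variance") <- mv$m
  attr(out, "m_mean") <- mm$m
  attr(out, "bonferroni_threshold") <- mv$bonferroni_threshold
  class(out) <- c("meta_stats", class(out))
  out
}
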