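#' Build a covariate design matrix from a sample sheet
#'
#' Dummy-encodes categorical batch variables, keeps numeric covariates as-is
#' and drops the last cell-proportion column (the proportions sum to one, so
#' keeping all of them makes the design rank-deficient with the intercept).
#' Rows with missing covariates are dropped with a message.
#'
#' @param samplesheet Sample sheet.
#' @param covariates Character vector of covariate column names;
#'   `cell_prop_*` columns are picked up automatically when `cells = TRUE`.
#' @param cells Include cell-proportion columns (all but the last).
#' @return list(X = design matrix incl. intercept, rows = kept row indices).
#' @keywords internal
build_design <- function(samplesheet,
                         covariates = c("horvath_age", "predicted_sex",
                                        "smoking_score", "sentrix_id",
                                        "sentrix_position"),
                         cells = TRUE) {
  covariates <- intersect(covariates, names(samplesheet))
  cell_cols <- grep("^cell_prop_", names(samplesheet), value = TRUE)
  if (cells && length(cell_cols) > 1L)
    covariates <- c(covariates, cell_cols[-length(cell_cols)])
  df <- samplesheet[, covariates, drop = FALSE]
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  # single-level factors carry no information and break model.matrix
  keep <- vapply(df, function(x) !is.factor(x) || nlevels(droplevels(x)) > 1L, TRUE)
  df <- df[, keep, drop = FALSE]
  ok <- stats::complete.cases(df)
  if (!all(ok)) message(sum(!ok), " samples dropped for missing covariates")
  df <- droplevels(df[ok, , drop = FALSE])
  X <- if (ncol(df)) stats::model.matrix(~ ., data = df)
       else matrix(1, sum(ok), 1, dimnames = list(NULL, "(Intercept)"))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank-deficient; collinear columns: ", paste(bad, collapse = ", "))
  }
  list(X = X, rows = which(ok))
}

#' Residualise beta values on a covariate design
#'
#' Per-probe OLS residuals of methylation beta values on a single shared
#' design of technical and biological covariates (sentrix ID/position, age,
#' sex, smoking score, cell proportions). The diagnosis label is never part
#' of the design: variance tests compare case vs control dispersion of these
#' residuals.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param samplesheet Sample sheet aligned to `colnames(beta)`.
#' @param covariates Covariate column names, as in [build_design()].
#' @return list of class `residual_matrix`: `residuals` (probe-by-sample),
#'   `design` (the model matrix), `samples` (IDs retained).
#' @export
residualize <- function(beta, samplesheet,
                        covariates = c("horvath_age", "predicted_sex",
                                       "smoking_score", "sentrix_id",
                                       "sentrix_position")) {
  samplesheet <- samplesheet[match(colnames(beta), samplesheet$sample_id), , drop = FALSE]
  d <- build_design(samplesheet, covariates)
  X <- d$X
  B <- beta[, d$rows, drop = FALSE]
  qx <- qr(X)
  R <- t(qr.resid(qx, t(B)))
  out <- list(residuals = R, design = X, samples = colnames(B))
  class(out) <- "residual_matrix"
  out
}

p_floor <- 1e-300

signed_z <- function(p, sign) {
  p <- pmax(p, p_floor)
  sign * stats::qnorm(1 - p / 2)
}

split_groups <- function(group) {
  g <- factor(group, levels = c("control", "case"))
  if (any(is.na(g))) stop("group labels must be 'control' or 'case'")
  list(ctrl = which(g == "control"), case = which(g == "case"))
}

#' Levene (Brown-Forsythe) test for equality of variances
#'
#' One-way ANOVA on absolute deviations from the group centre; the
#' median-centred (Brown-Forsythe) form is the default for robustness to
#' non-normality, with the mean-centred classical form as an option. The
#' returned Z is signed: positive when case dispersion exceeds control
#' dispersion, with |Z| = qnorm(1 - P/2).
#'
#' @param x Numeric values (typically covariate residuals at one probe).
#' @param group Labels "control"/"case".
#' @param center "median" (default) or "mean".
#' @return list(statistic, p.value, z, df); NA statistic when within-group
#'   deviations are all zero.
#' @export
levene_test <- function(x, group, center = c("median", "mean")) {
  center <- match.arg(center)
  idx <- split_groups(group)
  r <- row_levene(matrix(x, nrow = 1), idx$case, idx$ctrl, center)
  list(statistic = r$statistic, p.value = r$p.value, z = r$z,
       df = c(1L, length(x) - 2L))
}

#' Bartlett's test for equality of variances
#'
#' The classical chi-squared statistic on log pooled vs group variances;
#' sensitive but assumes normality. Signed Z as in [levene_test()], with the
#' sign taken from case minus control sample variance.
#'
#' @inheritParams levene_test
#' @return list(statistic, p.value, z); NA when any group variance is zero.
#' @export
bartlett_test <- function(x, group) {
  idx <- split_groups(group)
  r <- row_bartlett(matrix(x, nrow = 1), idx$case, idx$ctrl)
  list(statistic = r$statistic, p.value = r$p.value, z = r$z)
}

#' Fligner-Killeen test for equality of variances
#'
#' Rank-based test on normal scores of absolute deviations from group
#' medians; highly robust to departures from normality. Signed Z as in
#' [levene_test()], sign from the case-minus-control mean normal score.
#'
#' @inheritParams levene_test
#' @return list(statistic, p.value, z); NA when ties leave the scores with
#'   zero variance.
#' @export
fligner_killeen_test <- function(x, group) {
  idx <- split_groups(group)
  r <- row_fligner(matrix(x, nrow = 1), idx$case, idx$ctrl)
  list(statistic = r$statistic, p.value = r$p.value, z = r$z)
}

# ---- vectorised row-wise engines (k = 2 groups) ----

row_center <- function(M, center) {
  if (center == "median") matrixStats::rowMedians(M) else rowMeans(M)
}

row_levene <- function(R, case_idx, ctrl_idx, center = "median") {
  n1 <- length(ctrl_idx); n2 <- length(case_idx); N <- n1 + n2; k <- 2L
  Z1 <- abs(R[, ctrl_idx, drop = FALSE] - row_center(R[, ctrl_idx, drop = FALSE], center))
  Z2 <- abs(R[, case_idx, drop = FALSE] - row_center(R[, case_idx, drop = FALSE], center))
  m1 <- rowMeans(Z1); m2 <- rowMeans(Z2)
  mg <- (n1 * m1 + n2 * m2) / N
  ss_between <- n1 * (m1 - mg)^2 + n2 * (m2 - mg)^2
  ss_within <- rowSums((Z1 - m1)^2) + rowSums((Z2 - m2)^2)
  W <- ((N - k) / (k - 1)) * ss_between / ss_within
  bad <- ss_within <= 0
  W[bad] <- NA_real_
  p <- stats::pf(W, k - 1, N - k, lower.tail = FALSE)
  data.frame(statistic = W, p.value = p, z = signed_z(p, sign(m2 - m1)))
}

row_bartlett <- function(R, case_idx, ctrl_idx) {
  n1 <- length(ctrl_idx); n2 <- length(case_idx); N <- n1 + n2; k <- 2L
  v1 <- matrixStats::rowVars(R[, ctrl_idx, drop = FALSE])
  v2 <- matrixStats::rowVars(R[, case_idx, drop = FALSE])
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (N - k)
  C <- 1 + (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (N - k)) / (3 * (k - 1))
  T <- ((N - k) * log(sp2) - (n1 - 1) * log(v1) - (n2 - 1) * log(v2)) / C
  bad <- v1 <= 0 | v2 <= 0
  T[bad] <- NA_real_
  p <- stats::pchisq(T, k - 1, lower.tail = FALSE)
  data.frame(statistic = T, p.value = p, z = signed_z(p, sign(v2 - v1)))
}

row_fligner <- function(R, case_idx, ctrl_idx) {
  n1 <- length(ctrl_idx); n2 <- length(case_idx); N <- n1 + n2; k <- 2L
  A1 <- abs(R[, ctrl_idx, drop = FALSE] -
              matrixStats::rowMedians(R[, ctrl_idx, drop = FALSE]))
  A2 <- abs(R[, case_idx, drop = FALSE] -
              matrixStats::rowMedians(R[, case_idx, drop = FALSE]))
  A <- cbind(A1, A2)
  rk <- matrixStats::rowRanks(A, ties.method = "average")
  a <- stats::qnorm(0.5 + rk / (2 * (N + 1)))
  abar <- rowMeans(a)
  va <- matrixStats::rowVars(a)
  m1 <- rowMeans(a[, seq_len(n1), drop = FALSE])
  m2 <- rowMeans(a[, n1 + seq_len(n2), drop = FALSE])
  stat <- (n1 * (m1 - abar)^2 + n2 * (m2 - abar)^2) / va
  bad <- !is.finite(va) | va <= 0
  stat[bad] <- NA_real_
  p <- stats::pchisq(stat, k - 1, lower.tail = FALSE)
  data.frame(statistic = stat, p.value = p, z = signed_z(p, sign(m2 - m1)))
}

#' Mean-effect EWAS by multiple linear regression
#'
#' Per probe, ordinary least squares with methylation beta value as outcome
#' and the diagnosis indicator plus covariates as predictors. The effect size
#' is the diagnosis coefficient (case - control, on the beta-value scale),
#' with its standard error, a two-sided t-distribution P-value and
#' Z = beta/SE. All probes share one design, so the fit is a single
#' multi-response least-squares solve.
#'
#' @inheritParams residualize
#' @return data.frame(probe_id, beta, se, z, p.value, df).
#' @export
mean_ewas <- function(beta, samplesheet,
                      covariates = c("horvath_age", "predicted_sex",
                                     "smoking_score", "sentrix_id",
                                     "sentrix_position")) {
  samplesheet <- samplesheet[match(colnames(beta), samplesheet$sample_id), , drop = FALSE]
  d <- build_design(samplesheet, covariates)
  diag01 <- as.numeric(samplesheet$diagnosis[d$rows] == "case")
  X <- cbind(d$X, diagnosis = diag01)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design with diagnosis term is rank-deficient")
  Y <- t(beta[, d$rows, drop = FALSE])
  cf <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  n <- nrow(X); pcol <- ncol(X); df <- n - pcol
  sigma2 <- colSums(res^2) / df
  XtX_inv_jj <- chol2inv(chol(crossprod(X)))[pcol, pcol]
  b <- cf["diagnosis", ]
  se <- sqrt(sigma2 * XtX_inv_jj)
  tstat <- b / se
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(probe_id = rownames(beta), beta = unname(b), se = unname(se),
             z = unname(b / se), p.value = unname(p), df = df,
             stringsAsFactors = FALSE)
}

#' Per-cohort association scan: variance tests plus mean-effect EWAS
#'
#' Residualises beta values on the covariate design, runs the selected
#' variance tests on the residuals (case vs control), and fits the
#' mean-effect EWAS as a single multiple regression per probe. Degenerate
#' probes (zero within-group dispersion) are carried through as NA rows with
#' a reason code rather than dropped.
#'
#' @inheritParams residualize
#' @param tests Which variance tests to run.
#' @param center Centring for the Levene test.
#' @return data.frame of class `cohort_stats`: probe_id, n_case, n_control,
#'   `<test>_stat`/`_p`/`_z` columns, mean-effect beta/se/z_mean/p_mean and
#'   na_reason. Attribute `n_total` carries the analysed sample count used as
#'   the meta-analysis weight.
#' @export
run_cohort_association <- function(beta, samplesheet,
                                   covariates = c("horvath_age", "predicted_sex",
                                                  "smoking_score", "sentrix_id",
                                                  "sentrix_position"),
                                   tests = c("levene", "bartlett", "fligner"),
                                   center = "median") {
  tests <- match.arg(tests, c("levene", "bartlett", "fligner"), several.ok = TRUE)
  rz <- residualize(beta, samplesheet, covariates)
  ss <- samplesheet[match(rz$samples, samplesheet$sample_id), , drop = FALSE]
  idx <- split_groups(ss$diagnosis)
  if (length(idx$case) < 2L || length(idx$ctrl) < 2L)
    stop("need at least 2 cases and 2 controls")
  out <- data.frame(probe_id = rownames(beta),
                    n_case = length(idx$case), n_control = length(idx$ctrl),
                    stringsAsFactors = FALSE)
  R <- rz$residuals
  if ("levene" %in% tests) {
    lv <- row_levene(R, idx$case, idx$ctrl, center)
    out$levene_stat <- lv$statistic; out$levene_p <- lv$p.value; out$levene_z <- lv$z
  }
  if ("bartlett" %in% tests) {
    bt <- row_bartlett(R, idx$case, idx$ctrl)
    out$bartlett_stat <- bt$statistic; out$bartlett_p <- bt$p.value; out$bartlett_z <- bt$z
  }
  if ("fligner" %in% tests) {
    fk <- row_fligner(R, idx$case, idx$ctrl)
    out$fligner_stat <- fk$statistic; out$fligner_p <- fk$p.value; out$fligner_z <- fk$z
  }
  me <- mean_ewas(beta, samplesheet, covariates)
  out$beta <- me$beta; out$se <- me$se; out$z_mean <- me$z; out$p_mean <- me$p.value
  stat_cols <- intersect(paste0(c("levene", "bartlett", "fligner"), "_stat"), names(out))
  degenerate <- Reduce(`|`, lapply(stat_cols, function(cn) is.na(out[[cn]])))
  out$na_reason <- ifelse(degenerate, "degenerate dispersion", "")
  attr(out, "n_total") <- length(idx$case) + length(idx$ctrl)
  class(out) <- c("cohort_stats", class(out))
  out
}
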