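#' Simulation configuration for multi-cohort methylation studies
#'
#' Defines the stated world for the synthetic-data generator: cohort sizes,
#' planted variance-ratio and mean-shift effects, covariate effect-size
#' distributions, batch structure and noise levels. Values are generated on a
#' latent logit scale where covariate and variance effects are additive, then
#' mapped to beta values through the logistic function, so planted effects are
#' exactly recoverable by linear residualisation.
#'
#' @param n_cohorts Number of case-control cohorts.
#' @param n_cases,n_controls Per-cohort group sizes (recycled to `n_cohorts`).
#'   Defaults are the post-QC sizes of three schizophrenia case-control blood
#'   methylation cohorts (414/432, 339/322, 283/200).
#' @param n_probes Number of CpG probes.
#' @param fraction_vmp_up,fraction_vmp_down Fractions of probes planted with
#'   increased / decreased case residual variance. Defaults split planted VMPs
#'   roughly 65/35 towards increased variance.
#' @param fraction_dmp Fraction of probes planted with a case mean shift.
#' @param variance_ratio Case/control residual variance ratio at variance-up
#'   probes (variance-down probes use its reciprocal). Must be positive.
#' @param mean_shift Latent-scale (logit) mean shift added to cases at planted
#'   mean-shift probes; the sign is randomised per probe.
#' @param age_slope_sd,sex_offset_sd,smoking_slope_sd,cell_weight_sd Standard
#'   deviations of per-probe covariate coefficients on the latent scale.
#' @param n_cell_types Number of cell-type proportion columns.
#' @param n_batches Number of chips (sentrix IDs) per cohort.
#' @param batch_sd SD of per-batch latent mean offsets (mean offsets only; no
#'   batch-variance effects).
#' @param latent_mean_range Range of per-probe baseline latent means.
#' @param residual_sd_range Range of per-probe control residual SDs.
#' @param detection_failure_rate Fraction of matrix entries with detection
#'   P-value > 0.01.
#' @param seed Integer master seed; per-cohort and per-stage substreams are
#'   derived from it deterministically.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 3L,
                       n_cases = c(414L, 339L, 283L),
                       n_controls = c(432L, 322L, 200L),
                       n_probes = 20000L,
                       fraction_vmp_up = 0.00325,
                       fraction_vmp_down = 0.00175,
                       fraction_dmp = 0.005,
                       variance_ratio = 2,
                       mean_shift = 0.1,
                       age_slope_sd = 0.005,
                       sex_offset_sd = 0.1,
                       smoking_slope_sd = 0.05,
                       cell_weight_sd = 0.5,
                       n_cell_types = 3L,
                       n_batches = 8L,
                       batch_sd = 0.1,
                       latent_mean_range = c(-2.5, 2.5),
                       residual_sd_range = c(0.2, 0.6),
                       detection_failure_rate = 0.001,
                       seed = 1L) {
  n_cohorts <- as.integer(n_cohorts)
  stopifnot(n_cohorts >= 1L, n_probes >= 1L)
  n_cases <- as.integer(rep_len(n_cases, n_cohorts))
  n_controls <- as.integer(rep_len(n_controls, n_cohorts))
  if (any(n_cases < 2L) || any(n_controls < 2L))
    stop("each cohort needs at least 2 cases and 2 controls")
  fr <- c(fraction_vmp_up, fraction_vmp_down, fraction_dmp)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("effect fractions must lie in [0,1] and sum to at most 1")
  if (variance_ratio <= 0) stop("variance_ratio must be positive")
  if (detection_failure_rate < 0 || detection_failure_rate > 1)
    stop("detection_failure_rate must lie in [0,1]")
  stopifnot(length(latent_mean_range) == 2L, length(residual_sd_range) == 2L,
            all(residual_sd_range > 0))
  cfg <- list(
    n_cohorts = n_cohorts, n_cases = n_cases, n_controls = n_controls,
    n_probes = as.integer(n_probes),
    fraction_vmp_up = fraction_vmp_up, fraction_vmp_down = fraction_vmp_down,
    fraction_dmp = fraction_dmp,
    variance_ratio = variance_ratio, mean_shift = mean_shift,
    age_slope_sd = age_slope_sd, sex_offset_sd = sex_offset_sd,
    smoking_slope_sd = smoking_slope_sd, cell_weight_sd = cell_weight_sd,
    n_cell_types = as.integer(n_cell_types),
    n_batches = as.integer(n_batches), batch_sd = batch_sd,
    latent_mean_range = latent_mean_range,
    residual_sd_range = residual_sd_range,
    detection_failure_rate = detection_failure_rate,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-stage substreams below 2^31. Stage 0 = probe-level
# parameters (shared across cohorts so planted effects line up for
# meta-analysis); stage i = cohort i sample-level draws.
sim_seed <- function(config, stage) {
  (config$seed %% 100000L) * 10000L + 77L * as.integer(stage)
}

probe_ids <- function(n) sprintf("cg%07d", seq_len(n))

#' Probe-level ground truth and generative parameters
#'
#' Draws the per-probe parameters shared by every cohort of a study: effect
#' class (null / variance_up / variance_down / mean_shift), variance ratios,
#' latent mean shifts, baseline means, residual SDs and covariate
#' coefficients. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `truth` (data.frame: probe_id, effect_class,
#'   rho, delta) and the latent-model coefficient vectors/matrices.
#' @export
simulate_probe_params <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, 0L))
  p <- config$n_probes
  n_up <- round(config$fraction_vmp_up * p)
  n_dn <- round(config$fraction_vmp_down * p)
  n_dmp <- round(config$fraction_dmp * p)
  idx <- sample.int(p, n_up + n_dn + n_dmp)
  effect_class <- rep("null", p)
  effect_class[idx[seq_len(n_up)]] <- "variance_up"
  effect_class[idx[n_up + seq_len(n_dn)]] <- "variance_down"
  effect_class[idx[n_up + n_dn + seq_len(n_dmp)]] <- "mean_shift"
  rho <- rep(1, p)
  rho[effect_class == "variance_up"] <- config$variance_ratio
  rho[effect_class == "variance_down"] <- 1 / config$variance_ratio
  delta <- rep(0, p)
  is_dmp <- effect_class == "mean_shift"
  delta[is_dmp] <- config$mean_shift * sample(c(-1, 1), sum(is_dmp), replace = TRUE)
  list(
    truth = data.frame(probe_id = probe_ids(p), effect_class = effect_class,
                       rho = rho, delta = delta, stringsAsFactors = FALSE),
    mu = stats::runif(p, config$latent_mean_range[1], config$latent_mean_range[2]),
    sigma = stats::runif(p, config$residual_sd_range[1], config$residual_sd_range[2]),
    age_slope = stats::rnorm(p, 0, config$age_slope_sd),
    sex_offset = stats::rnorm(p, 0, config$sex_offset_sd),
    smoke_slope = stats::rnorm(p, 0, config$smoking_slope_sd),
    cell_weights = matrix(stats::rnorm(p * config$n_cell_types, 0, config$cell_weight_sd),
                          nrow = p))
}

#' Generate one synthetic case-control methylation cohort
#'
#' Latent model per probe j and sample i:
#' \deqn{m_{ij} = \mu_j + a_j age_i + s_j sex_i + k_j smoke_i +
#'   \sum_c w_{jc} cell_{ic} + b_{batch(i)} + case_i \Delta_j + \epsilon_{ij}}
#' with \eqn{\epsilon_{ij} \sim N(0, \sigma_j^2)} for controls and
#' \eqn{N(0, \sigma_j^2 \rho_j)} for cases, and beta value
#' \eqn{\beta_{ij} = 1/(1+e^{-m_{ij}})}. Ground truth is returned alongside so
#' downstream recovery can be scored.
#'
#' @param config A [sim_config()].
#' @param cohort_index Cohort number in `1:n_cohorts`.
#' @param keep_latent If `TRUE`, the latent noise matrix `epsilon` is kept on
#'   the result (for oracle checks of planted variance ratios).
#' @return A list of class `sim_cohort` with elements `beta`, `detp`
#'   (probe-by-sample matrices), `intensity` (per-sample median M/U signal),
#'   `samplesheet`, `truth`, and optionally `epsilon`.
#' @export
generate_cohort <- function(config, cohort_index, keep_latent = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cohort_index <- as.integer(cohort_index)
  if (cohort_index < 1L || cohort_index > config$n_cohorts)
    stop("cohort_index out of range")
  pp <- simulate_probe_params(config)
  set.seed(sim_seed(config, cohort_index))
  p <- config$n_probes
  n_case <- config$n_cases[cohort_index]
  n_ctrl <- config$n_controls[cohort_index]
  n <- n_case + n_ctrl
  diagnosis <- c(rep("control", n_ctrl), rep("case", n_case))
  case01 <- as.numeric(diagnosis == "case")
  sample_id <- sprintf("C%02d_S%04d", cohort_index, seq_len(n))

  # demographics: male excess among cases, slight smoking elevation in cases,
  # granulocyte-dominant cell mixture -- mirrors blood cohorts of this kind
  male <- stats::rbinom(n, 1, ifelse(case01 == 1, 0.62, 0.55))
  age <- pmin(pmax(stats::rnorm(n, 50, 10), 18), 90)
  smoke <- stats::rnorm(n, 0, 1) + 0.3 * case01
  shp <- c(6, 3, 1)[seq_len(config$n_cell_types)]
  if (config$n_cell_types > 3L) shp <- c(shp, rep(1, config$n_cell_types - 3L))
  cells <- matrix(stats::rgamma(n * config$n_cell_types, shape = rep(shp, each = n)),
                  nrow = n)
  cells <- cells / rowSums(cells)
  colnames(cells) <- sprintf("cell_prop_%d", seq_len(config$n_cell_types))
  batch <- sample.int(config$n_batches, n, replace = TRUE)
  batch_offset <- stats::rnorm(config$n_batches, 0, config$batch_sd)
  sentrix_id <- sprintf("SX%02d%02d", cohort_index, batch)
  sentrix_position <- sprintf("R%02dC%02d", sample.int(6, n, replace = TRUE),
                              sample.int(2, n, replace = TRUE))

  age_c <- age - 50  # centred so mu stays the operating point
  m <- matrix(pp$mu, p, n) +
    tcrossprod(pp$age_slope, age_c) +
    tcrossprod(pp$sex_offset, male) +
    tcrossprod(pp$smoke_slope, smoke) +
    pp$cell_weights %*% t(cells - matrix(colMeans(cells), n, ncol(cells), byrow = TRUE)) +
    matrix(batch_offset[batch], p, n, byrow = TRUE) +
    tcrossprod(pp$truth$delta, case01)
  sd_mat <- tcrossprod(pp$sigma, rep(1, n))
  case_cols <- which(case01 == 1)
  sd_mat[, case_cols] <- sd_mat[, case_cols] * sqrt(pp$truth$rho)
  eps <- matrix(stats::rnorm(p * n), p, n) * sd_mat
  beta <- stats::plogis(m + eps)
  dimnames(beta) <- list(probe_ids(p), sample_id)

  detp <- matrix(1e-4, p, n, dimnames = dimnames(beta))
  n_fail <- round(config$detection_failure_rate * length(detp))
  if (n_fail > 0) detp[sample.int(length(detp), n_fail)] <- 0.5

  intensity <- data.frame(
    sample_id = sample_id,
    median_methylated = pmax(stats::rnorm(n, 6000, 800), 3000),
    median_unmethylated = pmax(stats::rnorm(n, 6000, 800), 3000),
    stringsAsFactors = FALSE)

  samplesheet <- data.frame(
    sample_id = sample_id,
    cohort = sprintf("cohort%02d", cohort_index),
    diagnosis = diagnosis,
    reported_sex = ifelse(male == 1, "male", "female"),
    predicted_sex = ifelse(male == 1, "male", "female"),
    horvath_age = age,
    smoking_score = smoke,
    sentrix_id = sentrix_id,
    sentrix_position = sentrix_position,
    stringsAsFactors = FALSE)
  samplesheet <- cbind(samplesheet, as.data.frame(cells))

  out <- list(beta = beta, detp = detp, intensity = intensity,
              samplesheet = samplesheet, truth = pp$truth)
  if (keep_latent) out$epsilon <- eps
  class(out) <- "sim_cohort"
  out
}

#' Generate a synthetic 450K-manifest-style probe annotation
#'
#' Probes are placed on autosomes (a configurable fraction on chrX, flagged
#' non-autosomal), with a configurable fraction organised into tight genomic
#' clusters so that multi-probe regions exist; the rest sit on a sparse 10 kb
#' grid so no two unclustered probes fall within a region window. Blacklist
#' flags mirror the standard array exclusion lists (non-autosomal, non-CpG,
#' cross-hybridising, SNP within 5 nt).
#'
#' @param n_probes Number of probes; IDs match [generate_cohort()].
#' @param cluster_fraction Fraction of probes placed in clusters.
#' @param cluster_size Probes per cluster.
#' @param cluster_width Maximum span of a cluster in bp.
#' @param frac_non_autosomal,frac_non_cpg,frac_cross_hyb,frac_snp Blacklist
#'   flag fractions.
#' @param n_genes Size of the synthetic nearest-gene catalogue.
#' @param seed Integer seed.
#' @return data.frame with columns probe_id, chr, pos, nearest_gene,
#'   genic_feature, cpg_relation and logical flag_* columns.
#' @export
generate_annotation <- function(n_probes,
                                cluster_fraction = 0.2,
                                cluster_size = 5L,
                                cluster_width = 400L,
                                frac_non_autosomal = 0.02,
                                frac_non_cpg = 0.01,
                                frac_cross_hyb = 0.02,
                                frac_snp = 0.02,
                                n_genes = 2000L,
                                seed = 1L) {
  stopifnot(n_probes >= 1)
  set.seed(as.integer(seed) %% 100000L * 10000L + 9901L)
  n <- as.integer(n_probes)
  n_clustered <- round(cluster_fraction * n)
  n_clusters <- n_clustered %/% cluster_size
  n_clustered <- n_clusters * cluster_size

  grid <- seq(10000L, 200000000L, by = 10000L)
  chr <- character(n); pos <- integer(n)
  autosomes <- sprintf("chr%d", 1:22)
  slots <- sample(grid, (n - n_clustered) + n_clusters)
  loose_pos <- slots[seq_len(n - n_clustered)]
  centers <- slots[(n - n_clustered) + seq_len(n_clusters)]
  chr_loose <- sample(autosomes, n - n_clustered, replace = TRUE)
  chr_centers <- sample(autosomes, n_clusters, replace = TRUE)
  cl_pos <- integer(0); cl_chr <- character(0)
  for (ci in seq_len(n_clusters)) {
    offs <- sort(sample.int(cluster_width, cluster_size))
    cl_pos <- c(cl_pos, centers[ci] + offs)
    cl_chr <- c(cl_chr, rep(chr_centers[ci], cluster_size))
  }
  chr <- c(chr_loose, cl_chr)
  pos <- c(loose_pos, cl_pos)

  non_auto <- stats::runif(n) < frac_non_autosomal
  chr[non_auto] <- "chrX"

  genes <- sprintf("GENE%05d", seq_len(n_genes))
  ann <- data.frame(
    probe_id = probe_ids(n),
    chr = chr, pos = pos,
    nearest_gene = sample(genes, n, replace = TRUE),
    genic_feature = sample(c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                             "3'UTR", "Intergenic"), n, replace = TRUE,
                           prob = c(0.12, 0.08, 0.08, 0.05, 0.35, 0.07, 0.25)),
    cpg_relation = sample(c("Island", "N_Shore", "S_Shore", "N_Shelf",
                            "S_Shelf", "OpenSea"), n, replace = TRUE,
                          prob = c(0.3, 0.12, 0.12, 0.05, 0.05, 0.36)),
    flag_non_autosomal = non_auto,
    flag_non_cpg = stats::runif(n) < frac_non_cpg,
    flag_cross_hybridising = stats::runif(n) < frac_cross_hyb,
    flag_snp_within_5nt = stats::runif(n) < frac_snp,
    stringsAsFactors = FALSE)
  ann
}

#' Generate a synthetic external EWAS-catalogue table
#'
#' For each trait, samples a probe set and constructs standardised effect
#' sizes with a specified expected Pearson correlation against the supplied
#' meta-analysis Z-scores: \eqn{e = r z^* + \sqrt{1-r^2}\,\eta} with
#' \eqn{z^*} the standardised Z-scores and \eqn{\eta} standard normal noise.
#' Traits with fewer than `min_probes` probes are emitted but flagged, so the
#' covariance layer's exclusion rule can be exercised.
#'
#' @param meta_z Named numeric vector of Z-scores (names = probe IDs).
#' @param trait_specs data.frame with columns trait, n_probes, target_r.
#' @param min_probes Reporting threshold recorded in the `below_threshold`
#'   flag (default 10).
#' @param seed Integer seed.
#' @return data.frame with columns trait, probe_id, effect, below_threshold.
#' @export
generate_external_catalog <- function(meta_z, trait_specs, min_probes = 10L,
                                      seed = 1L) {
  stopifnot(is.numeric(meta_z), !is.null(names(meta_z)),
            all(c("trait", "n_probes", "target_r") %in% names(trait_specs)))
  set.seed(as.integer(seed) %% 100000L * 10000L + 3307L)
  out <- vector("list", nrow(trait_specs))
  for (i in seq_len(nrow(trait_specs))) {
    k <- trait_specs$n_probes[i]
    r <- trait_specs$target_r[i]
    if (k > length(meta_z))
      stop("trait '", trait_specs$trait[i], "' requests ", k,
           " probes but only ", length(meta_z), " are available")
    stopifnot(abs(r) <= 1)
    pid <- sample(names(meta_z), k)
    zs <- as.numeric(scale(meta_z[pid]))
    eff <- r * zs + sqrt(1 - r^2) * stats::rnorm(k)
    out[[i]] <- data.frame(trait = trait_specs$trait[i], probe_id = pid,
                           effect = eff, below_threshold = k < min_probes,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
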