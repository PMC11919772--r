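#' Tissue-enriched gene sets from an expression table
#'
#' For each tissue, the top fraction of genes ranked by that tissue's
#' expression is deemed tissue-enriched. Ties at the cutoff are broken by
#' stable gene-ID order, so constant expression yields the first genes in
#' table order.
#'
#' @param expression Gene-by-tissue nonnegative numeric matrix or data.frame
#'   with gene IDs as rownames.
#' @param top_fraction Fraction of genes per set (default 0.05).
#' @return Named list of gene-ID character vectors, one per tissue.
#' @export
tissue_enriched_sets <- function(expression, top_fraction = 0.05) {
  expression <- as.matrix(expression)
  stopifnot(top_fraction > 0, top_fraction <= 1, !is.null(rownames(expression)))
  n_top <- max(1L, floor(top_fraction * nrow(expression)))
  genes <- rownames(expression)
  sets <- lapply(seq_len(ncol(expression)), function(j) {
    o <- order(-expression[, j], seq_along(genes))
    genes[o[seq_len(n_top)]]
  })
  names(sets) <- colnames(expression)
  sets
}

#' Fisher's exact enrichment of hits in gene or probe sets
#'
#' Two-sided Fisher's exact test of each set against the hit list within the
#' universe. Odds ratios are the sample (cross-product) OR with a
#' Haldane-Anscombe 0.5 correction applied when any cell is zero; 95% CIs
#' come from the Woolf log-OR standard error. When `z` is supplied, the
#' analysis is additionally stratified into positive-Z and negative-Z hits
#' (e.g. variance-up vs variance-down probes). BH correction is applied
#' across sets within each stratum.
#'
#' @param hits Character vector of significant genes/probes (subset of
#'   `universe`).
#' @param universe All tested genes/probes.
#' @param sets Named list of character vectors; members outside the universe
#'   are ignored, but a set fully disjoint from the universe is an error.
#' @param z Optional named numeric vector of Z-scores over `hits` used for
#'   direction stratification.
#' @return data.frame with stratum, set, 2x2 counts, odds_ratio, ci_lo,
#'   ci_hi, p.value, q.
#' @export
fisher_enrichment <- function(hits, universe, sets, z = NULL) {
  stopifnot(length(universe) > 0, all(hits %in% universe))
  strata <- list(all = hits)
  if (!is.null(z)) {
    strata$variance_up <- hits[z[hits] > 0]
    strata$variance_down <- hits[z[hits] < 0]
  }
  res <- list()
  for (sn in names(strata)) {
    h <- strata[[sn]]
    rows <- lapply(names(sets), function(nm) {
      s <- intersect(sets[[nm]], universe)
      if (length(s) == 0L)
        stop("set '", nm, "' is disjoint from the universe")
      a <- length(intersect(h, s))
      b <- length(h) - a
      cc <- length(s) - a
      d <- length(universe) - a - b - cc
      p <- stats::fisher.test(matrix(c(a, b, cc, d), 2), alternative = "two.sided")$p.value
      cells <- c(a, b, cc, d)
      if (any(cells == 0)) cells <- cells + 0.5
      or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
      se <- sqrt(sum(1 / cells))
      data.frame(stratum = sn, set = nm, hit_in = a, hit_out = b,
                 nonhit_in = cc, nonhit_out = d,
                 odds_ratio = or,
                 ci_lo = exp(log(or) - 1.96 * se),
                 ci_hi = exp(log(or) + 1.96 * se),
                 p.value = p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q <- stats::p.adjust(tab$p.value, method = "BH")
    res[[sn]] <- tab
  }
  do.call(rbind, res)
}

#' Phenome-wide epigenetic covariance against an external EWAS catalogue
#'
#' For each catalogued trait, intersects its reported probes with the
#' meta-analysis table, standardises the trait's effect sizes to zero mean
#' and unit variance, and computes the Pearson correlation (with two-sided P)
#' against the meta-analysis Z-scores at those probes. Traits with fewer than
#' `min_probes` intersecting probes are excluded; traits with fewer than two
#' are skipped with a message. BH correction across traits, plus the
#' Bonferroni line 0.05 / n_traits.
#'
#' @param meta_z Named numeric vector of meta-analysis Z-scores.
#' @param catalog data.frame(trait, probe_id, effect).
#' @param min_probes Minimum intersecting probes per trait (default 10).
#' @return data.frame(trait, n_probes, r, p.value, q,
#'   bonferroni_significant) with attribute `bonferroni_threshold`.
#' @export
epigenetic_covariance <- function(meta_z, catalog, min_probes = 10L) {
  stopifnot(!is.null(names(meta_z)),
            all(c("trait", "probe_id", "effect") %in% names(catalog)))
  rows <- list()
  for (tr in unique(catalog$trait)) {
    cat_t <- catalog[catalog$trait == tr, ]
    cat_t <- cat_t[cat_t$probe_id %in% names(meta_z), ]
    if (nrow(cat_t) < 2L) {
      message("trait '", tr, "' has <2 intersecting probes; skipped")
      next
    }
    if (nrow(cat_t) < min_probes) next
    eff <- as.numeric(scale(cat_t$effect))
    ct <- stats::cor.test(meta_z[cat_t$probe_id], eff, method = "pearson")
    rows[[tr]] <- data.frame(trait = tr, n_probes = nrow(cat_t),
                             r = unname(ct$estimate), p.value = ct$p.value,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(trait = character(0), n_probes = integer(0),
                      r = numeric(0), p.value = numeric(0), q = numeric(0),
                      bonferroni_significant = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p.value, method = "BH")
  thr <- 0.05 / nrow(out)
  out$bonferroni_significant <- out$p.value < thr
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Correlation of Z-scores between two sets of summary statistics
#'
#' Pearson correlation of per-probe Z-scores over a shared probe subset;
#' used for replication checks and cross-phenotype comparisons.
#'
#' @param stats_a,stats_b data.frames with probe_id and a Z column.
#' @param z_col Z column name (default "z_meta").
#' @param probe_subset Optional probe IDs to restrict to.
#' @return list(r, p.value, n).
#' @export
zscore_correlation <- function(stats_a, stats_b, z_col = "z_meta",
                               probe_subset = NULL) {
  shared <- intersect(stats_a$probe_id, stats_b$probe_id)
  if (!is.null(probe_subset)) shared <- intersect(shared, probe_subset)
  if (length(shared) < 3L) stop("fewer than 3 shared probes")
  za <- stats_a[[z_col]][match(shared, stats_a$probe_id)]
  zb <- stats_b[[z_col]][match(shared, stats_b$probe_id)]
  ok <- is.finite(za) & is.finite(zb)
  if (sum(ok) < 3L) stop("fewer than 3 shared probes with finite Z")
  ct <- stats::cor.test(za[ok], zb[ok], method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = sum(ok))
}
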