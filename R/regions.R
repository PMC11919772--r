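#' Distance-binned autocorrelation of probe-level Z-scores
#'
#' Pearson correlation of Z-scores between probe pairs, binned by genomic
#' distance, pooled across chromosomes. Negative estimates are truncated to
#' zero, since the correlation matrix used for Stouffer-Liptak combination
#' must stay positive.
#'
#' @param z Numeric Z-scores.
#' @param chr,pos Chromosome and position per probe.
#' @param max_lag_bp Largest pair distance considered (default 1000).
#' @param bin_width Distance bin width in bp (default 100).
#' @return data.frame(lag_lo, lag_hi, correlation, n_pairs); lag 0 (self
#'   pairs) is 1 by construction and not listed.
#' @export
estimate_autocorrelation <- function(z, chr, pos, max_lag_bp = 1000L,
                                     bin_width = 100L) {
  stopifnot(length(z) == length(chr), length(z) == length(pos))
  pairs_a <- numeric(0); pairs_b <- numeric(0); dist <- numeric(0)
  for (cc in unique(chr)) {
    i <- which(chr == cc)
    if (length(i) < 2L) next
    o <- i[order(pos[i])]
    p <- pos[o]
    for (k in seq_along(o)) {
      j <- k + 1L
      while (j <= length(o) && p[j] - p[k] <= max_lag_bp) {
        pairs_a <- c(pairs_a, z[o[k]]); pairs_b <- c(pairs_b, z[o[j]])
        dist <- c(dist, p[j] - p[k])
        j <- j + 1L
      }
    }
  }
  if (!length(dist)) stop("no probe pairs within max_lag_bp on any chromosome")
  bin <- pmin(ceiling(dist / bin_width), ceiling(max_lag_bp / bin_width))
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    r <- if (sum(sel) >= 3L) suppressWarnings(stats::cor(pairs_a[sel], pairs_b[sel]))
         else NA_real_
    data.frame(lag_lo = (b - 1L) * bin_width, lag_hi = b * bin_width,
               correlation = max(0, r, na.rm = FALSE), n_pairs = sum(sel))
  }))
  out$correlation[is.na(out$correlation)] <- 0
  out
}

acf_lookup <- function(acf, d) {
  r <- numeric(length(d))
  for (i in seq_along(d)) {
    hit <- which(acf$lag_lo < d[i] & d[i] <= acf$lag_hi)
    r[i] <- if (length(hit)) acf$correlation[hit[1]] else 0
  }
  r
}

#' Stouffer-Liptak combination of signed Z-scores under correlation
#'
#' Combined Z = 1' z / sqrt(1' Sigma 1) with Sigma the pairwise correlation
#' matrix; reduces to plain Stouffer when Sigma is the identity. Two-sided P.
#'
#' @param z Signed Z-scores of the member probes.
#' @param sigma Correlation matrix (defaults to identity).
#' @return list(z, p.value).
#' @export
stouffer_liptak <- function(z, sigma = diag(length(z))) {
  stopifnot(nrow(sigma) == length(z), ncol(sigma) == length(z))
  zc <- sum(z) / sqrt(sum(sigma))
  list(z = zc, p.value = 2 * stats::pnorm(-abs(zc)))
}

#' Sidak correction for a region covering part of the tested span
#'
#' P_Sidak = 1 - (1 - P)^(total_span / region_span): the region's combined P
#' adjusted for the number of same-sized regions that tile the tested
#' genomic span. Equals P when the region covers the whole span.
#'
#' @param p Combined region P-value.
#' @param region_span,total_span Covered bases of the region and of all
#'   tested probes.
#' @return Adjusted P-value.
#' @export
sidak_correct <- function(p, region_span, total_span) {
  stopifnot(region_span > 0, total_span >= region_span)
  1 - (1 - p)^(total_span / region_span)
}

# union length of [pos - window, pos + window] intervals, per chromosome
covered_span <- function(chr, pos, window) {
  tot <- 0
  for (cc in unique(chr)) {
    p <- sort(pos[chr == cc])
    lo <- pmax(p - window, 1); hi <- p + window
    cur_lo <- lo[1]; cur_hi <- hi[1]
    for (i in seq_along(p)[-1]) {
      if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
      else { tot <- tot + (cur_hi - cur_lo + 1); cur_lo <- lo[i]; cur_hi <- hi[i] }
    }
    tot <- tot + (cur_hi - cur_lo + 1)
  }
  tot
}

#' Aggregate probe-level meta-analysis results into regions
#'
#' comb-p-style caller: probes with P below `seed_p` seed candidate regions,
#' which extend bidirectionally over neighbouring probes with P below
#' `extend_p` lying within `window_bp` of the previous member. Member
#' Z-scores are combined by Stouffer-Liptak using a correlation matrix
#' derived from the distance-binned autocorrelation of the input Z-scores,
#' and the combined P is Sidak-corrected for the ratio of the total tested
#' span (union of probe positions +/- window) to the region span. Regions
#' need at least `min_probes` members and P_Sidak below `alpha` to be
#' reported.
#'
#' @param meta data.frame with probe_id, z_meta, p_meta (e.g. [run_meta()]).
#' @param annotation Probe annotation with probe_id, chr, pos; probes missing
#'   from it are dropped with a warning.
#' @param seed_p,extend_p Seeding and extension P thresholds (defaults 0.05).
#' @param window_bp Maximum gap between consecutive member probes (500).
#' @param min_probes Minimum member count for a reported region (2).
#' @param alpha P_Sidak threshold (0.05).
#' @param acf Optional precomputed [estimate_autocorrelation()] table.
#' @return data.frame of regions (1-based inclusive coordinates): chr, start,
#'   end, n_probes, probe_ids, z_combined, p_combined, p_sidak, direction.
#' @export
find_regions <- function(meta, annotation, seed_p = 0.05, extend_p = 0.05,
                         window_bp = 500L, min_probes = 2L, alpha = 0.05,
                         acf = NULL) {
  m <- match(meta$probe_id, annotation$probe_id)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " probes missing from annotation were dropped")
    meta <- meta[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  chr <- annotation$chr[m]; pos <- annotation$pos[m]
  ok <- !is.na(meta$p_meta)
  meta <- meta[ok, , drop = FALSE]; chr <- chr[ok]; pos <- pos[ok]
  if (!nrow(meta)) return(empty_regions())
  if (is.null(acf))
    acf <- tryCatch(estimate_autocorrelation(meta$z_meta, chr, pos,
                                             max_lag_bp = window_bp),
                    error = function(e) NULL)
  total_span <- covered_span(chr, pos, window_bp)

  out <- list()
  for (cc in unique(chr)) {
    i <- which(chr == cc)
    o <- i[order(pos[i])]
    p <- meta$p_meta[o]; z <- meta$z_meta[o]; x <- pos[o]
    used <- rep(FALSE, length(o))
    for (s in which(p < seed_p)) {
      if (used[s]) next
      lo <- s
      while (lo > 1L && !used[lo - 1L] && p[lo - 1L] < extend_p &&
             x[lo] - x[lo - 1L] <= window_bp) lo <- lo - 1L
      hi <- s
      while (hi < length(o) && !used[hi + 1L] && p[hi + 1L] < extend_p &&
             x[hi + 1L] - x[hi] <= window_bp) hi <- hi + 1L
      used[lo:hi] <- TRUE
      mem <- lo:hi
      if (length(mem) < min_probes) next
      sig <- diag(length(mem))
      if (!is.null(acf)) {
        for (a in seq_along(mem)) for (b in seq_along(mem)) {
          if (a != b) sig[a, b] <- acf_lookup(acf, abs(x[mem[a]] - x[mem[b]]))
        }
      }
      comb <- stouffer_liptak(z[mem], sig)
      span <- x[mem[length(mem)]] - x[mem[1]] + 1
      ps <- sidak_correct(comb$p.value, span, total_span)
      out[[length(out) + 1L]] <- data.frame(
        chr = cc, start = x[mem[1]], end = x[mem[length(mem)]],
        n_probes = length(mem),
        probe_ids = paste(meta$probe_id[o[mem]], collapse = ";"),
        z_combined = comb$z, p_combined = comb$p.value, p_sidak = ps,
        direction = if (comb$z > 0) "+" else "-",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_regions())
  res <- do.call(rbind, out)
  res <- res[res$p_sidak < alpha, , drop = FALSE]
  res[order(res$p_sidak), , drop = FALSE]
}

empty_regions <- function() {
  data.frame(chr = character(0), start = integer(0), end = integer(0),
             n_probes = integer(0), probe_ids = character(0),
             z_combined = numeric(0), p_combined = numeric(0),
             p_sidak = numeric(0), direction = character(0),
             stringsAsFactors = FALSE)
}
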