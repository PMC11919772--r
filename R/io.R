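header_comment <- function(seed = NULL) {
  sprintf("# methvar %s | generated %s%s",
          as.character(utils::packageVersion("methvar")),
          format(Sys.time(), "%Y-%m-%d"),
          if (is.null(seed)) "" else sprintf(" | seed %d", as.integer(seed)))
}

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Read / write a probe-by-sample matrix as (gzipped) TSV
#'
#' Probes as rows, first column `probe_id`, header row of sample IDs.
#' Comment lines starting with `#` are skipped on read. Duplicate probe IDs
#' are an error.
#'
#' @param path File path; `.gz` suffix triggers gzip compression.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id") stop("malformed header: first column must be probe_id")
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup)) stop("duplicate probe IDs: ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}

#' @rdname read_beta_matrix
#' @param x Matrix to write.
#' @param seed Optional seed recorded in the header comment.
#' @export
write_beta_matrix <- function(x, path, seed = NULL) {
  con <- open_out(path); on.exit(close(con))
  writeLines(header_comment(seed), con)
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write a sample sheet as CSV
#'
#' Duplicate sample IDs are an error on read.
#' @param path File path.
#' @return data.frame.
#' @export
read_samplesheet <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("malformed sample sheet: no sample_id column")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample IDs: ", paste(unique(dup), collapse = ", "))
  df
}

#' @rdname read_samplesheet
#' @param x data.frame to write.
#' @param seed Optional seed recorded in the header comment.
#' @export
write_samplesheet <- function(x, path, seed = NULL) {
  con <- open_out(path); on.exit(close(con))
  writeLines(header_comment(seed), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a probe annotation table as CSV
#'
#' Columns mirror 450K-manifest naming: probe_id, chr, pos, nearest_gene,
#' genic_feature, cpg_relation plus logical flag_* columns. Coordinates are
#' 1-based inclusive (manifest convention).
#' @param path File path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("probe_id", "chr", "pos")
  if (!all(need %in% names(df)))
    stop("malformed annotation: need columns ", paste(need, collapse = ", "))
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup)) stop("duplicate probe ID in annotation: ",
                        paste(unique(dup), collapse = ", "))
  for (fc in grep("^flag_", names(df), value = TRUE)) df[[fc]] <- as.logical(df[[fc]])
  df
}

#' @rdname read_annotation
#' @param x data.frame to write.
#' @param seed Optional seed recorded in the header comment.
#' @export
write_annotation <- function(x, path, seed = NULL) {
  con <- open_out(path); on.exit(close(con))
  writeLines(header_comment(seed), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Tab-separated: set name, description, then member genes.
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  con <- open_out(path); on.exit(close(con))
  for (nm in names(sets))
    writeLines(paste(c(nm, nm, sets[[nm]]), collapse = "\t"), con)
  invisible(path)
}

#' Read / write genomic intervals in BED format
#'
#' BED is 0-based half-open on disk; in memory, intervals are 1-based
#' inclusive (manifest convention), so the reader adds 1 to starts and the
#' writer subtracts 1.
#' @param path File path.
#' @return data.frame(chr, start, end, name) with 1-based inclusive
#'   coordinates.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chr", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "name"
  if (any(df$start < 0) || any(df$end <= df$start))
    stop("BED coordinate violation: need 0 <= start < end")
  df$start <- df$start + 1L
  df
}

#' @rdname read_bed
#' @param x data.frame with 1-based inclusive chr/start/end (+ extra
#'   columns).
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chr", "start", "end") %in% names(x)))
  out <- x
  out$start <- out$start - 1L
  con <- open_out(path); on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write per-probe summary statistics as TSV
#'
#' One row per probe; columns as produced by [run_cohort_association()] or
#' [run_meta()]. A `#`-prefixed header records package version and seed.
#' @param path File path.
#' @return data.frame.
#' @export
read_summary_stats <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname read_summary_stats
#' @param x data.frame to write.
#' @param seed Optional seed recorded in the header comment.
#' @export
write_summary_stats <- function(x, path, seed = NULL) {
  con <- open_out(path); on.exit(close(con))
  writeLines(header_comment(seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
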