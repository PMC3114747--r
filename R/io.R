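#' Read a per-SNP allele-signal table (BeadStudio-style TSV)
#'
#' Reads a tab-separated table with header columns `chrom`, `pos` (1-based),
#' `baf` and `log_r` (optional `a_signal`, `b_signal` columns are carried
#' through). Rows with non-finite `baf` or `log_r` are dropped with a
#' message stating the count.
#'
#' @param path Path to the TSV file.
#' @return A [locus_profile()] with `chrom` and `pos` columns.
#' @export
read_signal_tsv <- function(path) {
  check_that(file.exists(path), paste("file not found:", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("baf", "log_r")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    fail_validation(paste("signal TSV is missing required column(s):",
                          paste(missing_cols, collapse = ", ")))
  }
  keep <- is.finite(df$baf) & is.finite(df$log_r)
  if (any(!keep)) {
    message("read_signal_tsv: dropped ", sum(!keep),
            " row(s) with non-finite baf/log_r")
    df <- df[keep, , drop = FALSE]
  }
  check_that(nrow(df) >= 1, "signal TSV contains no usable rows")
  prof <- locus_profile(beta = df$baf, log_r = df$log_r,
                        chrom = if (is.null(df$chrom)) NULL else df$chrom,
                        pos = if (is.null(df$pos)) NULL else df$pos)
  if (!is.null(df$a_signal)) prof$a_signal <- df$a_signal[]
  if (!is.null(df$b_signal)) prof$b_signal <- df$b_signal[]
  prof
}

#' Write a per-SNP allele-signal table
#'
#' Writes the TSV dialect read by [read_signal_tsv()]: columns `chrom`,
#' `pos` (1-based), `baf`, `log_r` and, when available, `a_signal` /
#' `b_signal`.
#'
#' @param x A [locus_profile()] or a `cna_sim` (its profile is written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_tsv <- function(x, path) {
  if (inherits(x, "cna_sim")) x <- x$profile
  x <- as_profile_df(x)
  n <- nrow(x)
  out <- data.frame(chrom = if (is.null(x$chrom)) rep("sim", n) else x$chrom,
                    pos = if (is.null(x$pos)) seq_len(n) else x$pos,
                    baf = x$beta, log_r = x$log_r)
  if (!is.null(x$a_signal)) out$a_signal <- x$a_signal
  if (!is.null(x$b_signal)) out$b_signal <- x$b_signal
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a three-state call track as a merged segment BED
#'
#' Merges maximal runs of identical state into intervals and writes them as
#' BED (0-based half-open) with the state in the name column. Interval
#' bounds come from the `pos` column when present (an interval covers
#' `[first_pos - 1, last_pos)`), otherwise from locus indices.
#'
#' @param calls A `"cna_calls"` object (or data.frame with `state` and
#'   optionally `chrom`, `pos`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(calls, path) {
  check_that(is.data.frame(calls) && !is.null(calls$state),
             "`calls` must carry a `state` column")
  n <- nrow(calls)
  check_that(n >= 1, "no calls to write")
  chrom <- if (is.null(calls$chrom)) rep("sim", n) else as.character(calls$chrom)
  pos <- if (is.null(calls$pos)) seq_len(n) else as.integer(calls$pos)
  key <- paste(chrom, as.character(calls$state), sep = "\r")
  runs <- rle(key)
  last <- cumsum(runs$lengths)
  first <- last - runs$lengths + 1
  seg <- data.frame(chrom = chrom[first],
                    start = pos[first] - 1L,
                    end = pos[last],
                    name = as.character(calls$state[first]))
  utils::write.table(seg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the simulator's ground-truth aberration blocks as BED
#'
#' One row per aberration block: `chrom`, `start`, `end` (0-based
#' half-open locus coordinates), aberration state (`gain`/`loss`), and the
#' 1-based subclone index.
#'
#' @param sim A `cna_sim` from [simulate_mixture()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(sim, path) {
  check_that(inherits(sim, "cna_sim"), "`sim` must be a cna_sim")
  rows <- list()
  for (i in seq_along(sim$truth_specs)) {
    for (s in sim$truth_specs[[i]]) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = "sim", start = s$start_locus,
        end = s$start_locus + s$length,
        name = aberration_sign(s$kind), subclone = i)
    }
  }
  bed <- do.call(rbind, rows)
  utils::write.table(bed[order(bed$start), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read exon boundaries in transcript coordinates from BED
#'
#' The BED chrom column holds the transcript identifier; `start`/`end` are
#' 0-based half-open positions within the transcript.
#'
#' @param path Path to a 3+ column BED file (no header).
#' @return A `data.frame` with `transcript_id`, `start`, `end` and
#'   `exon_index`, sorted and validated non-overlapping per transcript.
#' @export
read_exon_bed <- function(path) {
  check_that(file.exists(path), paste("file not found:", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  check_that(ncol(df) >= 3, "exon BED needs at least 3 columns")
  exons <- data.frame(transcript_id = as.character(df[[1]]),
                      start = as.integer(df[[2]]),
                      end = as.integer(df[[3]]))
  validate_exons(exons)
}

#' Read an RNA-seq variant-count table
#'
#' Tab-separated with header columns `transcript_id`, `pos`, `ref`, `alt`,
#' `ref_count`, `alt_count` (the dialect producible from a samtools pileup).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of variant sites.
#' @export
read_variant_tsv <- function(path) {
  check_that(file.exists(path), paste("file not found:", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("transcript_id", "pos", "ref_count", "alt_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    fail_validation(paste("variant TSV is missing required column(s):",
                          paste(missing_cols, collapse = ", ")))
  }
  df
}

#' Load a YAML run configuration
#'
#' Reads a YAML file of parameter overrides and merges it over the package
#' defaults (window 20, M-measure cutoff 0.1, SNR 30, heterozygosity 0.095,
#' 1000-locus blocks, 100-read RNA-seq filter, 200 replicates). Requires
#' the `yaml` package.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(seed = 1L, window = 20L, m_cutoff = 0.1,
                   logr_alpha = 0.01, logr_tolerance = 0.05,
                   snr = 30, n_loci = 10000L, het_prob = 0.095,
                   block_length = 1000L, min_reads = 100L,
                   n_reps = 200L, read_length = 50L)
  if (is.null(path)) return(defaults)
  check_that(file.exists(path), paste("file not found:", path))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is required to read configuration files",
         call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  check_that(is.list(user), "configuration must be a YAML mapping")
  utils::modifyList(defaults, user)
}
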