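#' Score per-nucleotide allelic imbalance in RNA-seq count tables
#'
#' Filters variant sites to those supported by at least `min_reads` reads
#' and scores each survivor by `0.5 - |0.5 - alt / (ref + alt)|`, the
#' folded non-reference allele fraction (0 = fully imbalanced, 0.5 =
#' perfectly balanced), with an exact binomial (Clopper-Pearson) confidence
#' interval on the alt fraction.
#'
#' If a logical `mask` column is present, masked sites (e.g. indel-adjacent
#' positions flagged upstream) are dropped before scoring.
#'
#' @param sites A `data.frame` with columns `transcript_id`, `pos`
#'   (1-based position in the transcript), `ref_count` and `alt_count`
#'   (non-negative integers); optional `ref`, `alt`, `mask` columns are
#'   carried through / honored.
#' @param min_reads Minimum supporting reads (default 100).
#' @param conf_level Confidence level of the binomial interval
#'   (default 0.95).
#' @return The filtered `data.frame` with added columns `alt_fraction`,
#'   `score`, `ci_low` and `ci_high`.
#' @export
#' @examples
#' score_sites(data.frame(transcript_id = "TX1", pos = 10,
#'                        ref_count = 150, alt_count = 50))$score  # 0.25
score_sites <- function(sites, min_reads = 100, conf_level = 0.95) {
  check_that(is.data.frame(sites), "`sites` must be a data.frame")
  check_that(all(c("ref_count", "alt_count") %in% names(sites)),
             "`sites` needs `ref_count` and `alt_count` columns")
  check_that(all(sites$ref_count >= 0) && all(sites$alt_count >= 0),
             "read counts must be non-negative")
  check_that(is.numeric(min_reads) && min_reads >= 1,
             "`min_reads` must be at least 1")
  if (!is.null(sites$mask)) sites <- sites[!isTRUE_vec(sites$mask), , drop = FALSE]
  total <- sites$ref_count + sites$alt_count
  sites <- sites[total >= min_reads, , drop = FALSE]
  if (nrow(sites) == 0) {
    sites$alt_fraction <- numeric(0)
    sites$score <- numeric(0)
    sites$ci_low <- numeric(0)
    sites$ci_high <- numeric(0)
    return(sites)
  }
  total <- sites$ref_count + sites$alt_count
  af <- sites$alt_count / total
  ci <- vapply(seq_len(nrow(sites)), function(i) {
    stats::binom.test(sites$alt_count[i], total[i],
                      conf.level = conf_level)$conf.int
  }, numeric(2))
  sites$alt_fraction <- af
  sites$score <- 0.5 - abs(0.5 - af)
  sites$ci_low <- ci[1, ]
  sites$ci_high <- ci[2, ]
  rownames(sites) <- NULL
  sites
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Detect within-exon fluctuations of allelic imbalance
#'
#' Emits a heterogeneity call for every pair of scored sites in the same
#' exon whose allelic imbalances differ significantly — evidence that the
#' underlying variants are carried by different subsets of subclones. In
#' `"ci"` mode (the default, mirroring a descriptive confidence-interval
#' display) a pair is called when the two Clopper-Pearson intervals on the
#' alt fraction are disjoint; in `"fisher"` mode pairwise Fisher exact tests
#' are corrected by Benjamini-Hochberg across all pairs and called at
#' `fisher_alpha`.
#'
#' Pairs closer than `read_length` are flagged (`within_read_length`): a
#' focal copy-number aberration shared by all subclones would shift both
#' sites of such a pair equally, so a discordant close pair argues against
#' that explanation.
#'
#' @param scored Output of [score_sites()].
#' @param exons Exon annotation: a `data.frame` with columns
#'   `transcript_id`, `start`, `end` (0-based half-open, transcript
#'   coordinates), e.g. from [read_exon_bed()].
#' @param read_length Read length in bp for the focal-CNA-exclusion flag
#'   (default 50).
#' @param method `"ci"` (disjoint confidence intervals) or `"fisher"`.
#' @param fisher_alpha BH-adjusted significance level for `"fisher"` mode
#'   (default 0.05).
#' @return A `data.frame` with one row per called pair: `transcript_id`,
#'   `exon_index`, `pos1`, `pos2`, `distance_bp`, `af1`, `af2`, `adjacent`
#'   (no passing site between the two), `within_read_length`, and in
#'   `"fisher"` mode `p_value` / `q_value`. Sites outside every exon are
#'   skipped with a warning.
#' @export
detect_exon_fluctuation <- function(scored, exons, read_length = 50,
                                    method = c("ci", "fisher"),
                                    fisher_alpha = 0.05) {
  method <- match.arg(method)
  check_that(is.data.frame(scored) &&
               all(c("transcript_id", "pos", "ref_count", "alt_count",
                     "ci_low", "ci_high", "alt_fraction") %in% names(scored)),
             "`scored` must come from score_sites()")
  check_that(is.data.frame(exons) &&
               all(c("transcript_id", "start", "end") %in% names(exons)),
             "`exons` needs transcript_id, start, end columns")
  exons <- validate_exons(exons)

  empty <- data.frame(transcript_id = character(0), exon_index = integer(0),
                      pos1 = integer(0), pos2 = integer(0),
                      distance_bp = integer(0), af1 = numeric(0),
                      af2 = numeric(0), adjacent = logical(0),
                      within_read_length = logical(0))
  if (nrow(scored) == 0) return(empty)

  exon_idx <- integer(nrow(scored))
  for (i in seq_len(nrow(scored))) {
    ex <- exons[exons$transcript_id == scored$transcript_id[i] &
                  exons$start < scored$pos[i] &
                  scored$pos[i] <= exons$end, , drop = FALSE]
    exon_idx[i] <- if (nrow(ex) >= 1) ex$exon_index[1] else NA_integer_
  }
  if (anyNA(exon_idx)) {
    warning(sum(is.na(exon_idx)),
            " site(s) fall outside every annotated exon and were skipped")
    scored <- scored[!is.na(exon_idx), , drop = FALSE]
    exon_idx <- exon_idx[!is.na(exon_idx)]
  }
  if (nrow(scored) < 2) return(empty)

  pairs <- list()
  groups <- split(seq_len(nrow(scored)),
                  paste(scored$transcript_id, exon_idx, sep = "\r"))
  for (g in groups) {
    if (length(g) < 2) next
    g <- g[order(scored$pos[g])]
    cmb <- utils::combn(g, 2)
    for (ci in seq_len(ncol(cmb))) {
      i <- cmb[1, ci]
      j <- cmb[2, ci]
      pairs[[length(pairs) + 1]] <- data.frame(
        transcript_id = scored$transcript_id[i],
        exon_index = exon_idx[i],
        i = i, j = j,
        pos1 = scored$pos[i], pos2 = scored$pos[j],
        distance_bp = abs(scored$pos[j] - scored$pos[i]),
        af1 = scored$alt_fraction[i], af2 = scored$alt_fraction[j],
        adjacent = which(g == i) + 1 == which(g == j))
    }
  }
  if (length(pairs) == 0) return(empty)
  pr <- do.call(rbind, pairs)
  pr$within_read_length <- pr$distance_bp < read_length

  if (method == "ci") {
    hit <- scored$ci_low[pr$i] > scored$ci_high[pr$j] |
      scored$ci_low[pr$j] > scored$ci_high[pr$i]
    out <- pr[hit, , drop = FALSE]
  } else {
    p <- vapply(seq_len(nrow(pr)), function(r) {
      i <- pr$i[r]
      j <- pr$j[r]
      stats::fisher.test(matrix(c(scored$ref_count[i], scored$alt_count[i],
                                  scored$ref_count[j], scored$alt_count[j]),
                                nrow = 2))$p.value
    }, numeric(1))
    q <- stats::p.adjust(p, method = "BH")
    pr$p_value <- p
    pr$q_value <- q
    out <- pr[q < fisher_alpha, , drop = FALSE]
  }
  out$i <- NULL
  out$j <- NULL
  rownames(out) <- NULL
  out
}

validate_exons <- function(exons) {
  check_that(all(exons$end > exons$start),
             "exon intervals must be non-empty (end > start)")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, , drop = FALSE]
    if (nrow(e) > 1) {
      check_that(all(e$start[-1] >= e$end[-nrow(e)]),
                 "exons of a transcript must not overlap")
    }
  }
  if (is.null(exons$exon_index)) {
    exons$exon_index <- stats::ave(exons$start, exons$transcript_id,
                                   FUN = seq_along)
  }
  exons
}

#' Simulate an RNA-seq variant-count fixture for a subclone mixture
#'
#' Emulates per-nucleotide read counts along one transcript for a mixture of
#' subclones: at a somatic site carried by a subset of subclones, the
#' non-reference allele probability is the summed fraction of the carrier
#' subclones; at a germline heterozygous site it is 0.5 in every subclone.
#' Read counts are binomial at the given depth.
#'
#' @param subclone_fractions Positive subclone abundances summing to 1.
#' @param somatic_pos Integer positions (1-based, transcript coordinates) of
#'   somatic variant sites.
#' @param somatic_carriers List (parallel to `somatic_pos`) of integer
#'   vectors: the subclones carrying each somatic variant.
#' @param germline_pos Integer positions of germline heterozygous sites.
#' @param depth Sequencing depth per site (default 1000).
#' @param transcript_id Transcript label (default `"TX1"`).
#' @param seed Optional integer seed.
#' @return A `data.frame` of variant sites (`transcript_id`, `pos`, `ref`,
#'   `alt`, `ref_count`, `alt_count`) with the planted alt probability in
#'   column `true_alt_prob`.
#' @export
#' @examples
#' # three equal subclones; variant carried by one at X1, by two at X2
#' fx <- generate_rnaseq_fixture(rep(1 / 3, 3),
#'                               somatic_pos = c(120, 180),
#'                               somatic_carriers = list(1, c(2, 3)),
#'                               germline_pos = 60, depth = 1000, seed = 1)
#' fx$true_alt_prob  # 0.5, 1/3, 2/3
generate_rnaseq_fixture <- function(subclone_fractions, somatic_pos = integer(0),
                                    somatic_carriers = list(),
                                    germline_pos = integer(0), depth = 1000,
                                    transcript_id = "TX1", seed = NULL) {
  fr <- as.numeric(subclone_fractions)
  check_that(length(fr) >= 1 && all(fr >= 0),
             "subclone fractions must be non-negative")
  check_that(abs(sum(fr) - 1) <= 1e-9, "subclone fractions must sum to 1")
  check_that(is_count(depth), "`depth` must be a positive integer")
  check_that(length(somatic_pos) == length(somatic_carriers),
             "one carrier set per somatic site is required")
  maybe_set_seed(seed)
  p_som <- vapply(somatic_carriers, function(cs) {
    cs <- as.integer(cs)
    check_that(length(cs) >= 1 && all(cs >= 1 & cs <= length(fr)),
               "carrier indices must reference existing subclones")
    sum(fr[unique(cs)])
  }, numeric(1))
  pos <- c(as.integer(germline_pos), as.integer(somatic_pos))
  p <- c(rep(0.5, length(germline_pos)), p_som)
  ord <- order(pos)
  pos <- pos[ord]
  p <- p[ord]
  n <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  alt_count <- stats::rbinom(n, depth, p)
  out <- data.frame(transcript_id = transcript_id, pos = pos, ref = ref,
                    alt = alt, ref_count = depth - alt_count,
                    alt_count = alt_count, true_alt_prob = p)
  rownames(out) <- NULL
  out
}
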