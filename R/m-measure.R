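#' Trigonometric per-SNP allelic-imbalance functions
#'
#' The per-SNP imbalance function scores the deviation of a B-allele
#' frequency from the three normal-state values \{0, 1/2, 1\}. The default,
#' `imbalance_sin2(beta) = sin(2*pi*beta)^2`, is a product of trigonometric
#' functions that is flat (zero slope) in a neighborhood of each normal-state
#' value — so its window mean is quadratically, not linearly, sensitive to
#' noise — and rises steeply past them, reaching 1 at `beta = 1/4` and
#' `beta = 3/4`. `imbalance_abs_sin(beta) = |sin(2*pi*beta)|` shares the
#' zeros and the maximum but has non-zero slope at the normal states.
#'
#' @param beta Numeric vector of B-allele frequencies.
#' @return Numeric vector of non-negative scores.
#' @export
imbalance_sin2 <- function(beta) sin(2 * pi * beta)^2

#' @rdname imbalance_sin2
#' @export
imbalance_abs_sin <- function(beta) abs(sin(2 * pi * beta))

# symmetric window half-widths, shrinking symmetrically at the edges
window_halfwidths <- function(n, window) {
  h <- window %/% 2L
  pmin(h, seq_len(n) - 1L, n - seq_len(n))
}

# windowed sums via cumulative sums over symmetric shrinking windows
window_sum <- function(x, hw) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  cs[idx + hw + 1L] - cs[idx - hw]
}

as_profile_df <- function(profile) {
  if (inherits(profile, "cna_sim")) profile <- profile$profile
  check_that(is.data.frame(profile) && "beta" %in% names(profile),
             "`profile` must be a locus_profile (or data.frame with `beta`)")
  check_that(nrow(profile) >= 1, "profile must cover at least one locus")
  profile
}

#' Windowed M-measure of allelic imbalance
#'
#' Scores each SNP by the mean per-SNP imbalance `f(beta)` over the symmetric
#' neighborhood of the `window` informative SNPs nearest to it. Informative
#' SNPs are those whose B-allele frequency lies strictly inside
#' `(hom_delta, 1 - hom_delta)` — homozygous loci sit on the outer bands and
#' carry no allelic-imbalance information, so windows are indexed over the
#' informative subsequence (a window of 20 then aggregates 20 actual
#' imbalance measurements regardless of local heterozygosity, which is what
#' makes the estimate robust). A non-informative SNP inherits the score of
#' its nearest informative neighbor; a profile without informative SNPs
#' scores 0 everywhere. Edge windows shrink symmetrically.
#'
#' @param profile A [locus_profile()] (or a `cna_sim`, whose profile is used).
#' @param window Window size `W` in informative SNPs (default 20).
#' @param imbalance_fn Per-SNP imbalance function of `beta`
#'   (default [imbalance_sin2()]).
#' @param hom_delta Half-width of the homozygous exclusion bands around 0 and
#'   1 (default 0.1).
#' @return Non-negative numeric vector of M-measure values, one per SNP.
#' @export
#' @examples
#' prof <- locus_profile(beta = rep(0.25, 30), rho = rep(1, 30))
#' m_measure(prof, window = 20)[15]  # 1: f(0.25) at its maximum
m_measure <- function(profile, window = 20, imbalance_fn = imbalance_sin2,
                      hom_delta = 0.1) {
  profile <- as_profile_df(profile)
  n <- nrow(profile)
  check_that(is_count(window), "`window` must be a positive integer")
  check_that(window <= n, "`window` must not exceed the number of loci")
  check_that(is.function(imbalance_fn), "`imbalance_fn` must be a function")
  beta <- profile$beta
  info <- which(is.finite(beta) & beta > hom_delta & beta < (1 - hom_delta))
  if (length(info) == 0) return(numeric(n))
  f <- imbalance_fn(beta[info])
  k <- length(f)
  hw <- window_halfwidths(k, min(window, k))
  m_info <- pmax(window_sum(f, hw) / (2 * hw + 1), 0)
  # each SNP inherits the score of its nearest informative SNP
  left <- findInterval(seq_len(n), info)        # rank of last informative <= j
  right <- pmin(left + 1L, k)                   # first informative >= j
  left <- pmax(left, 1L)
  d_left <- abs(seq_len(n) - info[left])
  d_right <- abs(info[right] - seq_len(n))
  nearest <- ifelse(d_left <= d_right, left, right)
  m_info[nearest]
}

#' Three-state copy-number classification from allelic imbalance and log-R
#'
#' The package's central fit: classifies every SNP as `gain`, `loss` or
#' `normal` from the combination of the windowed M-measure of allelic
#' imbalance and the windowed mean log-R ratio.
#'
#' A SNP is flagged aberrant when its M-measure exceeds `m_cutoff`, or when
#' the one-sided test of its windowed mean log-R being below 0 rejects at
#' level `logr_alpha` (this rescues hemizygous deletions carried by the
#' majority of cells, to which the M-measure is blind because the B-allele
#' frequency collapses onto the homozygous bands). Aberrant SNPs are labeled
#' `loss` when the windowed mean log-R is below `-logr_tolerance`, `gain`
#' when above `+logr_tolerance`, and `normal` otherwise (a copy-neutral
#' imbalance is not a copy-number event). All other SNPs are `normal`.
#'
#' The log-R noise scale for the test is estimated globally by the median
#' absolute deviation; loci with undefined log-R (zero total signal) enter
#' the windowed statistics at `log2(pmax(rho, rho_floor))` so homozygous
#' deletions retain their evidence.
#'
#' @inheritParams m_measure
#' @param m_cutoff M-measure threshold for the aberrance gate (default 0.1).
#' @param logr_alpha Significance level of the one-sided depressed-log-R test
#'   (default 0.01).
#' @param logr_tolerance Band around 0 of windowed mean log-R treated as "no
#'   total-DNA evidence" (default 0.05).
#' @param rho_floor Floor applied to `rho` when log-R is undefined
#'   (default `2^-10`).
#' @return An object of class `"cna_calls"`: a `data.frame` with columns
#'   `chrom`/`pos` (when present in the profile), `beta`, `log_r`, `m`,
#'   `log_r_mean` and `state` (factor gain/loss/normal), with the
#'   configuration in `attr(, "config")`.
#' @seealso [m_measure()], [viterbi_3smm()], [auc_roc_three_class()]
#' @export
#' @examples
#' sim <- simulate_mixture(alpha = 0.3, n_loci = 1000, block_length = 100,
#'                         seed = 7)
#' fit <- classify_cna(sim)
#' summary(fit)
classify_cna <- function(profile, window = 20, m_cutoff = 0.1,
                         logr_alpha = 0.01, logr_tolerance = 0.05,
                         imbalance_fn = imbalance_sin2, hom_delta = 0.1,
                         rho_floor = 2^-10) {
  profile <- as_profile_df(profile)
  check_that(is.numeric(m_cutoff) && m_cutoff > 0 && m_cutoff < 1,
             "`m_cutoff` must lie in (0, 1)")
  check_that(is.numeric(logr_alpha) && logr_alpha > 0 && logr_alpha < 1,
             "`logr_alpha` must lie in (0, 1)")
  check_that(is.numeric(logr_tolerance) && logr_tolerance >= 0,
             "`logr_tolerance` must be non-negative")
  check_that(!is.null(profile$log_r) || !is.null(profile$rho),
             "profile must carry `log_r` or `rho`")
  n <- nrow(profile)

  m <- m_measure(profile, window = window, imbalance_fn = imbalance_fn,
                 hom_delta = hom_delta)

  log_r <- if (is.null(profile$log_r)) {
    log2(pmax(profile$rho, rho_floor))
  } else {
    profile$log_r
  }
  logr_eff <- log_r
  bad <- !is.finite(logr_eff)
  if (any(bad)) {
    rho <- if (is.null(profile$rho)) rep(0, n) else profile$rho
    logr_eff[bad] <- log2(pmax(rho[bad], rho_floor))
  }

  hw <- window_halfwidths(n, min(window, n))
  n_win <- 2 * hw + 1
  logr_mean <- window_sum(logr_eff, hw) / n_win

  sigma <- max(stats::mad(logr_eff), 1e-12)
  z <- logr_mean * sqrt(n_win) / sigma
  depressed <- z < stats::qnorm(logr_alpha)

  aberrant <- (m > m_cutoff) | depressed
  state <- rep("normal", n)
  state[aberrant & logr_mean < -logr_tolerance] <- "loss"
  state[aberrant & logr_mean > logr_tolerance] <- "gain"

  new_cna_calls(profile, state = state, m = m, logr_mean = logr_mean,
                method = "m-measure",
                config = list(window = window, m_cutoff = m_cutoff,
                              logr_alpha = logr_alpha,
                              logr_tolerance = logr_tolerance,
                              hom_delta = hom_delta, rho_floor = rho_floor))
}

new_cna_calls <- function(profile, state, m, logr_mean, method, config) {
  df <- data.frame(beta = profile$beta,
                   log_r = if (is.null(profile$log_r)) NA_real_ else profile$log_r,
                   m = m, log_r_mean = logr_mean,
                   state = state_factor(state))
  if (!is.null(profile$pos)) df <- cbind(pos = profile$pos, df)
  if (!is.null(profile$chrom)) df <- cbind(chrom = profile$chrom, df)
  structure(df, class = c("cna_calls", "data.frame"),
            method = method, config = config)
}

#' @export
print.cna_calls <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Three-state CNA calls (", attr(x, "method"), ") over ", nrow(x),
      " SNPs\n", sep = "")
  if (!is.null(cfg$window)) {
    cat("  window =", cfg$window,
        if (!is.null(cfg$m_cutoff)) paste(", cutoff =", cfg$m_cutoff), "\n")
  }
  print(table(state = x$state))
  invisible(x)
}

#' @export
summary.cna_calls <- function(object, ...) {
  runs <- rle(as.character(object$state))
  seg <- data.frame(state = runs$values, n_snps = runs$lengths)
  out <- list(states = table(object$state),
              n_segments = nrow(seg),
              segments = seg,
              mean_m = tapply(object$m, object$state, mean),
              config = attr(object, "config"))
  class(out) <- "summary.cna_calls"
  out
}

#' @export
print.summary.cna_calls <- function(x, ...) {
  cat("Three-state CNA call summary\n")
  print(x$states)
  cat("segments:", x$n_segments, "\n")
  cat("mean M by state:\n")
  print(round(x$mean_m, 4))
  invisible(x)
}

#' @export
plot.cna_calls <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  cols <- c(gain = "firebrick", loss = "dodgerblue3", normal = "grey60")
  col <- cols[as.character(x$state)]
  graphics::plot(x$beta, pch = ".", col = col, ylab = "BAF", ylim = c(0, 1),
                 xlab = "", ...)
  graphics::plot(x$log_r, pch = ".", col = col, ylab = "log R", xlab = "", ...)
  graphics::plot(x$m, type = "l", ylab = "M-measure", xlab = "locus", ...)
  graphics::abline(h = attr(x, "config")$m_cutoff, lty = 2)
  invisible(x)
}

#' @export
as.data.frame.cna_calls <- function(x, ...) {
  class(x) <- "data.frame"
  attr(x, "method") <- NULL
  attr(x, "config") <- NULL
  x
}
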