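#' Simulate a germline genotype as a pair of haplotypes
#'
#' Each haplotype is a binary vector over loci (0 = A allele, 1 = B allele).
#' Loci are drawn independently: heterozygous with probability `het_prob`
#' (the two haplotypes then differ, with the B-carrying haplotype chosen at
#' random), otherwise homozygous with AA and BB equally likely. The default
#' heterozygosity of 9.5% is typical of a human SNP-array germline.
#'
#' @param n_loci Number of loci.
#' @param het_prob Per-locus heterozygosity probability in `[0, 1]`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `"haplotype_pair"` with binary integer vectors
#'   `h1`, `h2` and the logical vector `het`.
#' @export
#' @examples
#' g <- generate_germline(100, het_prob = 0.095, seed = 1)
#' mean(g$het)
generate_germline <- function(n_loci, het_prob = 0.095, seed = NULL) {
  check_that(is_count(n_loci), "`n_loci` must be a positive integer")
  check_that(is.numeric(het_prob) && length(het_prob) == 1 &&
               het_prob >= 0 && het_prob <= 1,
             "`het_prob` must lie in [0, 1]")
  maybe_set_seed(seed)
  het <- stats::runif(n_loci) < het_prob
  # homozygous loci: both haplotypes carry the same allele, AA or BB evenly;
  # heterozygous loci: one haplotype carries B, chosen by a fair coin.
  hom_allele <- as.integer(stats::runif(n_loci) < 0.5)
  het_b_on_h1 <- stats::runif(n_loci) < 0.5
  h1 <- ifelse(het, as.integer(het_b_on_h1), hom_allele)
  h2 <- ifelse(het, as.integer(!het_b_on_h1), hom_allele)
  structure(list(h1 = as.integer(h1), h2 = as.integer(h2), het = het,
                 n_loci = n_loci),
            class = "haplotype_pair")
}

#' @export
print.haplotype_pair <- function(x, ...) {
  cat("Germline haplotype pair over", x$n_loci, "loci;",
      sprintf("%.1f%%", 100 * mean(x$het)), "heterozygous\n")
  invisible(x)
}

#' Germline (stromal) genome from a haplotype pair
#'
#' Combines the two haplotypes into integer A/B copy counts; every locus has
#' total copy number 2.
#'
#' @param germline A [generate_germline()] result.
#' @return A [subclone_genome()].
#' @export
germline_genome <- function(germline) {
  check_that(inherits(germline, "haplotype_pair"),
             "`germline` must be a haplotype pair")
  subclone_genome(a_copies = (1L - germline$h1) + (1L - germline$h2),
                  b_copies = germline$h1 + germline$h2)
}

ABERRATION_KINDS <- c("homozygous_deletion", "hemizygous_deletion",
                      "gain_one", "gain_two")

#' Specify one aberration block
#'
#' @param kind One of `"homozygous_deletion"`, `"hemizygous_deletion"`,
#'   `"gain_one"`, `"gain_two"`.
#' @param start_locus 0-based index of the first affected locus.
#' @param length Number of consecutive affected loci (default 1000, roughly
#'   20 Mbp at SNP-array density).
#' @return A list of class `"aberration_spec"`.
#' @export
aberration_spec <- function(kind, start_locus, length = 1000) {
  kind <- match.arg(kind, ABERRATION_KINDS)
  check_that(is.numeric(start_locus) && length(start_locus) == 1 &&
               start_locus >= 0 && start_locus == floor(start_locus),
             "`start_locus` must be a non-negative integer (0-based)")
  check_that(is_count(length), "`length` must be a positive integer")
  structure(list(kind = kind, start_locus = as.integer(start_locus),
                 length = as.integer(length)),
            class = "aberration_spec")
}

spec_range <- function(spec) {
  # 0-based half-open [start, start + length)
  c(spec$start_locus, spec$start_locus + spec$length)
}

#' Apply aberration blocks to a germline, producing one tumor subclone
#'
#' Builds the integer copy vectors of a homogeneous tumor component by
#' editing the germline haplotypes block-wise: a homozygous deletion removes
#' both haplotypes, a hemizygous deletion removes one parental haplotype
#' (chosen by a seeded fair coin per block, so a block forms a coherent
#' B-allele-frequency band), and a gain duplicates one randomly chosen
#' parental haplotype once or twice. Blocks of a subclone must not overlap.
#'
#' @param germline A [generate_germline()] result.
#' @param specs A list of [aberration_spec()] objects.
#' @param seed Optional integer seed for the per-block haplotype coins.
#' @return A [subclone_genome()]; the chosen haplotype per block is recorded
#'   in `attr(, "hap_choice")`.
#' @export
apply_aberrations <- function(germline, specs, seed = NULL) {
  check_that(inherits(germline, "haplotype_pair"),
             "`germline` must be a haplotype pair")
  check_that(is.list(specs), "`specs` must be a list of aberration specs")
  specs <- lapply(specs, function(s) {
    if (!inherits(s, "aberration_spec")) {
      s <- aberration_spec(s$kind, s$start_locus,
                           if (is.null(s$length)) 1000 else s$length)
    }
    s
  })
  n <- germline$n_loci
  if (length(specs) > 1) {
    rng <- t(vapply(specs, spec_range, numeric(2)))
    ord <- order(rng[, 1])
    check_that(all(rng[ord, 2][-length(specs)] <= rng[ord, 1][-1]),
               "aberration blocks within a subclone must not overlap")
  }
  for (s in specs) {
    check_that(spec_range(s)[2] <= n,
               "aberration block extends past the last locus")
  }
  maybe_set_seed(seed)
  # per-haplotype copy counts, edited block-wise
  c1 <- rep(1L, n)
  c2 <- rep(1L, n)
  hap_choice <- integer(length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    idx <- seq.int(s$start_locus + 1L, s$start_locus + s$length)
    pick <- if (stats::runif(1) < 0.5) 1L else 2L
    hap_choice[i] <- pick
    delta <- switch(s$kind,
                    homozygous_deletion = NA_integer_,
                    hemizygous_deletion = -1L,
                    gain_one = 1L,
                    gain_two = 2L)
    if (s$kind == "homozygous_deletion") {
      c1[idx] <- 0L
      c2[idx] <- 0L
    } else if (pick == 1L) {
      c1[idx] <- c1[idx] + delta
    } else {
      c2[idx] <- c2[idx] + delta
    }
  }
  a <- c1 * (1L - germline$h1) + c2 * (1L - germline$h2)
  b <- c1 * germline$h1 + c2 * germline$h2
  out <- subclone_genome(a, b)
  attr(out, "hap_choice") <- hap_choice
  out
}

# Block layout: four aberration kinds in `block` -locus runs separated by
# `block` normal loci, starting after one leading normal run. The second
# subclone's grid is shifted by half a block with the kinds reversed, so every
# overlap pairs a deletion with a duplication and each kind also occurs alone.
default_layout <- function(n_subclones, block = 1000L) {
  starts1 <- block * c(1L, 3L, 5L, 7L)
  s1 <- mapply(function(k, st) aberration_spec(k, st, block),
               ABERRATION_KINDS, starts1, SIMPLIFY = FALSE)
  if (n_subclones == 1) return(list(s1))
  starts2 <- starts1 + block %/% 2L
  s2 <- mapply(function(k, st) aberration_spec(k, st, block),
               rev(ABERRATION_KINDS), starts2, SIMPLIFY = FALSE)
  list(s1, s2)
}

layout_min_loci <- function(n_subclones, block = 1000L) {
  if (n_subclones == 1) 8L * block else 8L * block + block %/% 2L
}

aberration_sign <- function(kind) {
  ifelse(kind %in% c("homozygous_deletion", "hemizygous_deletion"),
         "loss", "gain")
}

state_factor <- function(x) {
  factor(x, levels = c("gain", "loss", "normal"))
}

#' Simulate an SNP-array-like mixture of stroma and tumor subclones
#'
#' Generates one germline, derives the stromal component and one or two tumor
#' subclones carrying the four aberration kinds (homozygous deletion,
#' hemizygous deletion, single-copy gain, two-copy gain) in `block_length`-locus
#' blocks separated by `block_length` normal loci, mixes the components
#' linearly, adds Gaussian channel noise, and transforms to B-allele
#' frequency / log-R coordinates.
#'
#' Mixing coefficients are `alpha` for the stroma and `1 - alpha` for a single
#' subclone, or `2(1 - alpha)/3` and `(1 - alpha)/3` for two subclones. The
#' per-locus truth label is the aberration state of the aberrant component
#' with the largest mixing coefficient covering that locus (normal if none).
#'
#' Noise is zero-mean Gaussian, added independently to the aggregate A and B
#' channels before the transform, with standard deviation
#' `rms(channel) / snr` (`snr_scale = "amplitude"`, the default) or
#' `rms(channel) / sqrt(snr)` (`snr_scale = "power"`). Negative noisy signals
#' are clamped at zero. `snr = Inf` gives a noiseless dataset.
#'
#' @param alpha Stromal mixing coefficient in `[0, 1]`.
#' @param n_subclones 1 or 2 tumor subclones.
#' @param snr Signal-to-noise ratio (default 30).
#' @param n_loci Number of loci (default 10000).
#' @param het_prob Germline heterozygosity (default 0.095).
#' @param block_length Loci per aberration block and per separating normal
#'   run (default 1000).
#' @param snr_scale `"amplitude"` (sd = rms/snr) or `"power"`
#'   (variance = mean power/snr).
#' @param seed Optional integer seed.
#' @return An object of class `"cna_sim"`: a list with elements `profile`
#'   (a [locus_profile()]), `truth` (factor gain/loss/normal per locus),
#'   `truth_specs` (aberration specs per subclone), `components`
#'   (stroma first), `coefficients`, and the generating parameters.
#' @export
#' @examples
#' sim <- simulate_mixture(alpha = 0.3, n_subclones = 1, n_loci = 1000,
#'                         block_length = 100, seed = 1)
#' table(sim$truth)
simulate_mixture <- function(alpha, n_subclones = 1, snr = 30,
                             n_loci = 10000, het_prob = 0.095,
                             block_length = 1000,
                             snr_scale = c("amplitude", "power"),
                             seed = NULL) {
  check_that(is.numeric(alpha) && length(alpha) == 1 &&
               alpha >= 0 && alpha <= 1,
             "`alpha` must lie in [0, 1]")
  check_that(n_subclones %in% c(1, 2), "`n_subclones` must be 1 or 2")
  check_that(is.numeric(snr) && length(snr) == 1 && snr > 0,
             "`snr` must be positive (Inf for noiseless)")
  check_that(is_count(n_loci), "`n_loci` must be a positive integer")
  check_that(is_count(block_length), "`block_length` must be a positive integer")
  snr_scale <- match.arg(snr_scale)
  block_length <- as.integer(block_length)
  check_that(n_loci >= layout_min_loci(n_subclones, block_length),
             sprintf("n_loci must be at least %d to host the block layout",
                     layout_min_loci(n_subclones, block_length)))
  maybe_set_seed(seed)

  germ <- generate_germline(n_loci, het_prob)
  stroma <- germline_genome(germ)
  specs <- default_layout(n_subclones, block_length)
  subclones <- lapply(specs, function(sp) apply_aberrations(germ, sp))

  coefficients <- if (n_subclones == 1) {
    c(alpha, 1 - alpha)
  } else {
    c(alpha, 2 * (1 - alpha) / 3, (1 - alpha) / 3)
  }
  aggregate <- mix_signals(c(list(stroma), subclones), coefficients)

  a <- aggregate$a
  b <- aggregate$b
  if (is.finite(snr)) {
    sd_a <- channel_noise_sd(a, snr, snr_scale)
    sd_b <- channel_noise_sd(b, snr, snr_scale)
    a <- pmax(a + stats::rnorm(n_loci, 0, sd_a), 0)
    b <- pmax(b + stats::rnorm(n_loci, 0, sd_b), 0)
  }
  profile <- to_profile(allele_signal(a, b))
  profile <- locus_profile(beta = profile$beta, rho = profile$rho,
                           log_r = profile$log_r,
                           chrom = rep("sim", n_loci), pos = seq_len(n_loci))

  truth <- truth_from_specs(specs, coefficients[-1], n_loci, alpha)

  structure(list(profile = profile, truth = truth, truth_specs = specs,
                 components = c(list(stroma), subclones),
                 coefficients = coefficients, alpha = alpha,
                 n_subclones = n_subclones, snr = snr,
                 snr_scale = snr_scale, n_loci = n_loci,
                 het_prob = het_prob, block_length = block_length,
                 germline = germ, seed = seed),
            class = "cna_sim")
}

channel_noise_sd <- function(x, snr, snr_scale) {
  rms <- sqrt(mean(x^2))
  if (snr_scale == "amplitude") rms / snr else rms / sqrt(snr)
}

# Per-locus truth: state of the aberrant component with the largest mixing
# coefficient covering the locus; normal where no aberration, and all-normal
# when the tumor fraction is zero.
truth_from_specs <- function(specs, tumor_coefs, n_loci, alpha) {
  truth <- rep("normal", n_loci)
  if (alpha < 1) {
    ord <- order(tumor_coefs)  # paint small coefficient first, dominant last
    for (i in ord) {
      for (s in specs[[i]]) {
        idx <- seq.int(s$start_locus + 1L, s$start_locus + s$length)
        truth[idx] <- aberration_sign(s$kind)
      }
    }
  }
  state_factor(truth)
}

#' @export
print.cna_sim <- function(x, ...) {
  cat("Simulated subclone mixture\n")
  cat("  loci:", x$n_loci, " stromal alpha:", x$alpha,
      " subclones:", x$n_subclones, "\n")
  cat("  coefficients:", paste(format(x$coefficients, digits = 3),
                               collapse = ", "), "\n")
  cat("  snr:", x$snr, paste0("(", x$snr_scale, ")"), "\n")
  print(table(truth = x$truth))
  invisible(x)
}

#' @export
plot.cna_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  cols <- c(gain = "firebrick", loss = "dodgerblue3", normal = "grey60")
  col <- cols[as.character(x$truth)]
  graphics::plot(x$profile$beta, pch = ".", col = col, ylab = "BAF",
                 xlab = "", ylim = c(0, 1), ...)
  graphics::plot(x$profile$log_r, pch = ".", col = col, ylab = "log R",
                 xlab = "locus", ...)
  invisible(x)
}
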