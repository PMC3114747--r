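#' Infer the stromal mixing coefficient from deletion loci
#'
#' Solves the binary stroma/tumor de-mixing system at loci harboring
#' deletions. At such a locus the measured aggregate copy number is
#' `c = x * 2 + (1 - x) * m`, where `x` is the stromal coefficient and
#' `m` is the integer tumor copy number, 1 for a hemizygous and 0 for a
#' homozygous deletion. Solving for each hypothesis gives the two candidates
#' `x = (c - m) / (2 - m)`, i.e. `c / 2` for `m = 0` and `c - 1` for
#' `m = 1`. Since one `x` must hold at every locus simultaneously, the
#' estimate is the mode of all pooled candidates (histogram bin center, bin
#' width `bin_width`; candidates outside `[0, 1]` are discarded, since
#' mixing coefficients are proportions). Each locus is then assigned the
#' tumor copy number whose candidate is nearer the estimate.
#'
#' @param profile A [locus_profile()] (or `cna_sim`); the aggregate copy
#'   number is `2 * rho`.
#' @param loss_loci Integer indices of loci classified as loss, typically
#'   `which(classify_cna(profile)$state == "loss")`.
#' @param bin_width Histogram bin width for the mode (default 0.01). Ties
#'   between equally filled bins are broken toward the bin with the smaller
#'   within-bin variance.
#' @return An object of class `"mixing_fit"`: a list with `x_hat`,
#'   `per_locus_m` (0/1 per usable locus), `candidates` (per-locus candidate
#'   pairs), `histogram`, and `n_loci_used`. `coef()` returns `x_hat`.
#' @export
#' @examples
#' prof <- locus_profile(beta = rep(0, 4), rho = c(1.3, 1.3, 0.6, 0.6) / 2)
#' coef(infer_mixing_coefficient(prof, loss_loci = 1:4))  # 0.3
infer_mixing_coefficient <- function(profile, loss_loci, bin_width = 0.01) {
  profile <- as_profile_df(profile)
  check_that(!is.null(profile$rho),
             "profile must carry `rho` (aggregate copy number / 2)")
  loss_loci <- as.integer(loss_loci)
  check_that(length(loss_loci) >= 1, "`loss_loci` must be non-empty")
  check_that(all(loss_loci >= 1 & loss_loci <= nrow(profile)),
             "`loss_loci` out of range")
  check_that(is.numeric(bin_width) && bin_width > 0 && bin_width <= 1,
             "`bin_width` must lie in (0, 1]")

  c_bar <- 2 * profile$rho[loss_loci]
  keep <- is.finite(c_bar) & c_bar < 2
  if (!any(keep)) {
    stop("no deletion loci: no supplied locus has aggregate copy number ",
         "below two", call. = FALSE)
  }
  loci <- loss_loci[keep]
  c_bar <- c_bar[keep]
  cand0 <- c_bar / 2    # homozygous-deletion hypothesis, m = 0
  cand1 <- c_bar - 1    # hemizygous-deletion hypothesis, m = 1

  pooled <- c(cand0, cand1)
  pooled <- pooled[pooled >= 0 & pooled <= 1]
  if (length(pooled) == 0) {
    stop("all candidate mixing coefficients fall outside [0, 1]",
         call. = FALSE)
  }
  # bins centered on multiples of bin_width, so exact (noiseless) candidate
  # values sit at bin centers instead of straddling bin edges
  breaks <- seq(-bin_width / 2, 1 + bin_width, by = bin_width)
  bin <- findInterval(pooled, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    within_var <- vapply(best, function(b) {
      v <- stats::var(pooled[bin == b])
      if (is.na(v)) 0 else v
    }, numeric(1))
    best <- best[which.min(within_var)]
  }
  x_hat <- (breaks[best] + breaks[best + 1]) / 2

  d0 <- abs(cand0 - x_hat)
  d1 <- abs(cand1 - x_hat)
  d0[cand0 < 0 | cand0 > 1] <- Inf
  d1[cand1 < 0 | cand1 > 1] <- Inf
  per_locus_m <- ifelse(d1 <= d0, 1L, 0L)

  structure(list(x_hat = x_hat,
                 per_locus_m = per_locus_m,
                 candidates = data.frame(locus = loci, c_bar = c_bar,
                                         cand_m0 = cand0, cand_m1 = cand1,
                                         m = per_locus_m),
                 histogram = list(counts = counts,
                                  mids = (breaks[-length(breaks)] +
                                            breaks[-1]) / 2),
                 n_loci_used = length(loci),
                 bin_width = bin_width),
            class = "mixing_fit")
}

#' @export
coef.mixing_fit <- function(object, ...) c(x = object$x_hat)

#' @export
print.mixing_fit <- function(x, ...) {
  cat("Stromal mixing-coefficient fit\n")
  cat("  x_hat =", format(x$x_hat, digits = 4),
      " (mode of", 2 * x$n_loci_used, "candidates from",
      x$n_loci_used, "deletion loci)\n")
  cat("  tumor copy number at those loci: ",
      sum(x$per_locus_m == 1), " hemizygous (m=1), ",
      sum(x$per_locus_m == 0), " homozygous (m=0)\n", sep = "")
  invisible(x)
}

# all nonzero binary profiles over s loci, as columns of an s x (2^s - 1)
# matrix
binary_profiles <- function(s) {
  n <- 2^s - 1
  out <- matrix(0, nrow = s, ncol = n)
  for (j in seq_len(n)) {
    out[, j] <- as.integer(intToBits(j))[seq_len(s)]
  }
  out
}

#' Exhaustively enumerate exact de-mixings of a binary aggregate signal
#'
#' Demonstrates the non-uniqueness of subclonal de-mixing: for an aggregate
#' allele signal over `s` loci, enumerates every set of `k` distinct
#' components with binary per-allele profiles (each allele channel one of
#' the `2^s - 1` nonzero binary vectors) and every positive coefficient
#' vector on the grid `coefficient_grid` summing to 1, and returns all
#' combinations that reproduce the aggregate exactly (tolerance `1e-9`).
#' Solutions are unique up to component permutation by construction.
#'
#' A mixture of two independent components is recovered uniquely, whereas
#' three or more components admit multiple exact reconstructions; this
#' enumeration is a demonstration device, not a production solver, and is
#' guarded to `s <= 12` loci and `k <= 4` components.
#'
#' @param aggregate An [allele_signal()] over `s` loci.
#' @param k Number of mixture components.
#' @param coefficient_grid Positive coefficient grid step (default 0.1);
#'   coefficients are positive multiples of the step.
#' @param tol Reconstruction tolerance per channel entry (default 1e-9).
#' @return A list of class `"demix_enumeration"` with `solutions` (each a
#'   list with `components` — a list of `a`/`b` binary vectors — and
#'   `coefficients`), `n_solutions`, and `search_space_size` (`2^s - 1`).
#' @export
enumerate_demixings <- function(aggregate, k, coefficient_grid = 0.1,
                                tol = 1e-9) {
  check_that(inherits(aggregate, "allele_signal"),
             "`aggregate` must be an allele_signal")
  s <- aggregate$n_loci
  check_that(is_count(k), "`k` must be a positive integer")
  check_that(s <= 12 && k <= 4,
             "exhaustive search guard: need s <= 12 loci and k <= 4 components")
  check_that(is.numeric(coefficient_grid) && coefficient_grid > 0 &&
               coefficient_grid <= 1,
             "`coefficient_grid` must lie in (0, 1]")

  profiles <- binary_profiles(s)
  n_prof <- ncol(profiles)
  # component c = (a-profile, b-profile); stack the two channels
  n_comp <- n_prof^2
  comp <- matrix(0, nrow = 2 * s, ncol = n_comp)
  comp[seq_len(s), ] <- profiles[, rep(seq_len(n_prof), times = n_prof)]
  comp[s + seq_len(s), ] <- profiles[, rep(seq_len(n_prof), each = n_prof)]
  target <- c(aggregate$a, aggregate$b)

  n_steps <- round(1 / coefficient_grid)
  check_that(abs(n_steps * coefficient_grid - 1) <= 1e-9,
             "`coefficient_grid` must divide 1")
  compositions <- grid_compositions(n_steps, k) * coefficient_grid

  solutions <- list()
  add_solution <- function(idx, coefs) {
    comps <- lapply(idx, function(i)
      list(a = comp[seq_len(s), i], b = comp[s + seq_len(s), i]))
    solutions[[length(solutions) + 1]] <<- list(components = comps,
                                                coefficients = coefs)
  }

  if (k == 1) {
    hit <- which(colSums(abs(comp - target)) <= tol * 2 * s)
    for (i in hit) add_solution(i, 1)
  } else {
    idx_sets <- utils::combn(n_comp, k)
    for (ci in seq_len(nrow(compositions))) {
      x <- compositions[ci, ]
      mixed <- comp[, idx_sets[1, ], drop = FALSE] * x[1]
      for (r in 2:k) {
        mixed <- mixed + comp[, idx_sets[r, ], drop = FALSE] * x[r]
      }
      hit <- which(colSums(abs(mixed - target)) <= tol * 2 * s)
      for (h in hit) add_solution(idx_sets[, h], x)
    }
  }

  structure(list(solutions = solutions,
                 n_solutions = length(solutions),
                 search_space_size = n_prof,
                 k = k, s = s, coefficient_grid = coefficient_grid),
            class = "demix_enumeration")
}

# all ordered vectors of k positive integers summing to n, as rows
grid_compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- list()
  recurse <- function(prefix, remaining, slots) {
    if (slots == 1) {
      if (remaining >= 1) out[[length(out) + 1]] <<- c(prefix, remaining)
      return(invisible(NULL))
    }
    for (v in seq_len(remaining - slots + 1)) {
      recurse(c(prefix, v), remaining - v, slots - 1)
    }
  }
  recurse(integer(0), n, k)
  do.call(rbind, out)
}

#' @export
print.demix_enumeration <- function(x, ...) {
  cat("Exhaustive de-mixing enumeration: k =", x$k, "components over",
      x$s, "loci (search space", x$search_space_size,
      "binary profiles per allele)\n")
  cat("  exact reconstructions found:", x$n_solutions, "\n")
  invisible(x)
}
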