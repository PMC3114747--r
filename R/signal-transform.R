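#' Aggregate allele signal
#'
#' Container for the per-locus aggregate A- and B-allele quantities of a
#' (possibly heterogeneous) sample, i.e. the average number of copies of each
#' allele over all cells. A homogeneous diploid cell population has
#' `a + b = 2` everywhere.
#'
#' @param a,b Non-negative numeric vectors of equal length: the aggregate A-
#'   and B-allele quantity per locus.
#' @return An object of class `"allele_signal"`: a list with elements `a`, `b`
#'   and `n_loci`.
#' @seealso [to_profile()], [mix_signals()]
#' @export
#' @examples
#' allele_signal(a = c(1, 2, 0), b = c(1, 0, 2))
allele_signal <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  check_that(length(a) == length(b), "`a` and `b` must have identical length")
  check_that(length(a) >= 1, "allele signal must cover at least one locus")
  check_that(all(is.finite(a)) && all(is.finite(b)),
             "allele signals must be finite")
  check_that(all(a >= 0) && all(b >= 0),
             "allele signals must be non-negative")
  structure(list(a = a, b = b, n_loci = length(a)), class = "allele_signal")
}

#' @export
print.allele_signal <- function(x, ...) {
  cat("Aggregate allele signal over", x$n_loci, "loci\n")
  cat("  mean total copy number:", format(mean(x$a + x$b), digits = 4), "\n")
  invisible(x)
}

#' Integer allele copy numbers of one homogeneous component
#'
#' A subclone (or the stromal component) is represented by integer per-locus
#' copy counts of the A and B alleles. The stromal component satisfies
#' `a + b = 2` at every locus.
#'
#' @param a_copies,b_copies Non-negative integer vectors of equal length.
#' @return An object of class `"subclone_genome"`.
#' @export
subclone_genome <- function(a_copies, b_copies) {
  check_that(length(a_copies) == length(b_copies),
             "copy vectors must have identical length")
  check_that(all(is.finite(a_copies)) && all(is.finite(b_copies)),
             "copy numbers must be finite")
  check_that(all(a_copies >= 0) && all(b_copies >= 0),
             "copy numbers must be non-negative")
  check_that(all(a_copies == floor(a_copies)) && all(b_copies == floor(b_copies)),
             "copy numbers must be integers")
  structure(list(a_copies = as.integer(a_copies),
                 b_copies = as.integer(b_copies),
                 n_loci = length(a_copies)),
            class = "subclone_genome")
}

#' @export
print.subclone_genome <- function(x, ...) {
  tot <- x$a_copies + x$b_copies
  cat("Subclone genome over", x$n_loci, "loci;",
      sum(tot != 2), "loci deviate from the diploid total\n")
  invisible(x)
}

#' Transform aggregate allele signals to B-allele frequency and log-R ratio
#'
#' Converts per-locus aggregate A/B allele quantities into the standard
#' SNP-array coordinates: the B-allele frequency `beta = b / (a + b)`, the
#' total-DNA enrichment `rho = (a + b) / 2` (1 for a normal diploid locus),
#' and `log_r = log2(rho)` (0 for a normal diploid locus).
#'
#' Loci with zero total signal (`a + b = 0`, e.g. a homozygous deletion in a
#' pure tumor) get `beta = 0.5` by convention, so that they carry no spurious
#' allelic-imbalance signal; their deletion evidence is carried by `rho = 0`,
#' with `log_r` set to `NA` (undefined).
#'
#' @param signal An [allele_signal()], a [subclone_genome()], or a list with
#'   numeric elements `a` and `b`.
#' @return A `data.frame` of class `c("locus_profile", "data.frame")` with
#'   columns `beta`, `rho` and `log_r`.
#' @export
#' @examples
#' to_profile(allele_signal(a = c(1, 2, 1), b = c(1, 0, 0.7)))
to_profile <- function(signal) {
  if (inherits(signal, "subclone_genome")) {
    signal <- allele_signal(signal$a_copies, signal$b_copies)
  } else if (!inherits(signal, "allele_signal")) {
    check_that(is.list(signal) && !is.null(signal$a) && !is.null(signal$b),
               "`signal` must be an allele_signal or a list with `a` and `b`")
    signal <- allele_signal(signal$a, signal$b)
  }
  tot <- signal$a + signal$b
  beta <- ifelse(tot > 0, signal$b / tot, 0.5)
  rho <- tot / 2
  log_r <- ifelse(rho > 0, log2(rho), NA_real_)
  locus_profile(beta = beta, rho = rho, log_r = log_r)
}

#' Construct a per-locus profile of B-allele frequency and log-R ratio
#'
#' @param beta B-allele frequency in `[0, 1]` per locus.
#' @param rho Total-DNA enrichment (non-negative; 1 = normal diploid). If
#'   missing it is derived as `2^log_r`.
#' @param log_r log2 of `rho`. If missing it is derived as `log2(rho)` (with
#'   `NA` where `rho = 0`).
#' @param chrom,pos Optional chromosome labels and 1-based positions.
#' @return A `data.frame` of class `c("locus_profile", "data.frame")`.
#' @export
locus_profile <- function(beta, rho = NULL, log_r = NULL,
                          chrom = NULL, pos = NULL) {
  beta <- as.numeric(beta)
  check_that(length(beta) >= 1, "profile must cover at least one locus")
  check_that(all(beta >= 0 & beta <= 1, na.rm = TRUE),
             "`beta` must lie in [0, 1]")
  if (is.null(rho) && is.null(log_r)) {
    fail_validation("at least one of `rho` and `log_r` is required")
  }
  if (is.null(rho)) rho <- 2^as.numeric(log_r)
  rho <- as.numeric(rho)
  if (is.null(log_r)) log_r <- ifelse(rho > 0, log2(rho), NA_real_)
  log_r <- as.numeric(log_r)
  check_that(length(rho) == length(beta) && length(log_r) == length(beta),
             "`beta`, `rho` and `log_r` must have identical length")
  check_that(all(rho >= 0, na.rm = TRUE), "`rho` must be non-negative")
  df <- data.frame(beta = beta, rho = rho, log_r = log_r)
  if (!is.null(pos)) df <- cbind(pos = as.integer(pos), df)
  if (!is.null(chrom)) df <- cbind(chrom = as.character(chrom), df)
  class(df) <- c("locus_profile", "data.frame")
  df
}

#' Forward mixture model: coefficient-weighted sum of component signals
#'
#' Computes the aggregate allele signal of a heterogeneous sample as the
#' mixing-coefficient-weighted sum of its homogeneous components' copy
#' vectors. This is the forward model of subclonal mixing: the measured
#' aggregate `(a, b)` is linear in the components.
#'
#' @param components A list of [subclone_genome()] or [allele_signal()]
#'   objects, all with the same number of loci.
#' @param coefficients Non-negative mixing coefficients, one per component,
#'   summing to 1 (tolerance `1e-9`).
#' @return An [allele_signal()].
#' @export
#' @examples
#' stroma <- subclone_genome(c(1, 1), c(1, 1))
#' tumor  <- subclone_genome(c(2, 0), c(1, 1))
#' mix_signals(list(stroma, tumor), c(0.7, 0.3))
mix_signals <- function(components, coefficients) {
  check_that(is.list(components) && length(components) >= 1,
             "`components` must be a non-empty list")
  coefficients <- as.numeric(coefficients)
  check_that(length(coefficients) == length(components),
             "one coefficient per component is required")
  check_that(all(is.finite(coefficients)) && all(coefficients >= 0),
             "coefficients must be non-negative")
  check_that(abs(sum(coefficients) - 1) <= 1e-9,
             "coefficients must sum to 1 (tolerance 1e-9)")
  comp_ab <- lapply(components, function(cmp) {
    if (inherits(cmp, "subclone_genome")) {
      list(a = as.numeric(cmp$a_copies), b = as.numeric(cmp$b_copies))
    } else if (inherits(cmp, "allele_signal")) {
      list(a = cmp$a, b = cmp$b)
    } else {
      check_that(is.list(cmp) && !is.null(cmp$a) && !is.null(cmp$b),
                 "components must carry `a` and `b` vectors")
      list(a = as.numeric(cmp$a), b = as.numeric(cmp$b))
    }
  })
  n <- length(comp_ab[[1]]$a)
  check_that(all(vapply(comp_ab, function(x) length(x$a) == n && length(x$b) == n,
                        logical(1))),
             "all components must cover the same number of loci")
  a <- numeric(n)
  b <- numeric(n)
  for (i in seq_along(comp_ab)) {
    a <- a + coefficients[i] * comp_ab[[i]]$a
    b <- b + coefficients[i] * comp_ab[[i]]$b
  }
  allele_signal(a, b)
}
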