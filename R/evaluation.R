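#' Three-class mean balanced accuracy (operative-point AUCROC)
#'
#' Scores a three-state call track against the truth. For each class
#' `c` in \{gain, loss, normal\} the balanced accuracy is
#' `(TP_c / P_c + TN_c / N_c) / 2`, where positives are the loci truly in
#' class `c`; the unweighted mean over the three classes is returned. A
#' class absent from both numerator roles uses the convention `0/0 = 1`, so
#' perfect calls on aberration-free data score 1.
#'
#' @param calls A `"cna_calls"` object, or a factor/character vector of
#'   per-locus states (`gain` / `loss` / `normal`).
#' @param truth A factor/character vector of true states aligned with
#'   `calls`, or a `cna_sim`.
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' auc_roc_three_class(c("gain", "loss"), c("gain", "loss"))  # 1
auc_roc_three_class <- function(calls, truth) {
  if (inherits(calls, "cna_calls")) calls <- calls$state
  if (inherits(truth, "cna_sim")) truth <- truth$truth
  calls <- state_factor(as.character(calls))
  truth <- state_factor(as.character(truth))
  check_that(length(calls) == length(truth),
             "`calls` and `truth` must be aligned")
  check_that(!anyNA(calls) && !anyNA(truth),
             "states must be gain, loss or normal")
  ba <- vapply(levels(truth), function(cl) {
    pos <- truth == cl
    p <- sum(pos)
    n <- sum(!pos)
    tpr <- if (p == 0) 1 else sum(pos & calls == cl) / p
    tnr <- if (n == 0) 1 else sum(!pos & calls != cl) / n
    (tpr + tnr) / 2
  }, numeric(1))
  mean(ba)
}

#' Built-in caller plugins for simulation experiments
#'
#' Callers map a simulated dataset to a per-locus state track. The
#' M-measure caller runs [classify_cna()]; the 3SMM caller fits HMM
#' parameters from the dataset's own truth (the best-case parameterization
#' for a simulation) and decodes with [viterbi_3smm()]; the oracle caller
#' echoes the truth and is useful as a scoring sanity check.
#'
#' @param ... Arguments forwarded to [classify_cna()] /
#'   [fit_hmm_from_truth()] and [viterbi_3smm()].
#' @return A function `(profile, truth) -> factor of states` suitable for
#'   the `callers` list of [run_mixture_experiment()].
#' @export
caller_mmeasure <- function(...) {
  function(profile, truth) classify_cna(profile, ...)$state
}

#' @rdname caller_mmeasure
#' @export
caller_3smm <- function(...) {
  function(profile, truth) {
    params <- fit_hmm_from_truth(profile, truth, ...)
    viterbi_3smm(profile, params, ...)$state
  }
}

#' @rdname caller_mmeasure
#' @export
caller_oracle <- function() {
  function(profile, truth) truth
}

#' Run a stroma/subclone mixture benchmark over a grid of mixing coefficients
#'
#' For every stromal coefficient in `alphas`, simulates `n_reps` independent
#' datasets with [simulate_mixture()] and scores each registered caller with
#' [auc_roc_three_class()]. A caller raising an error is recorded as a
#' failed cell and the run continues.
#'
#' @param alphas Stromal mixing coefficients to test.
#' @param n_reps Replicates per coefficient (default 200).
#' @param n_subclones 1 or 2 tumor subclones.
#' @param callers Named list of caller functions `(profile, truth) -> states`
#'   (see [caller_mmeasure()]).
#' @param seed Optional integer seed for the whole experiment (one RNG
#'   stream drives all replicates).
#' @param ... Further arguments to [simulate_mixture()] (e.g. `n_loci`,
#'   `snr`, `block_length`).
#' @return A `data.frame` with columns `alpha`, `caller`, `mean_auc`,
#'   `sd_auc`, `n_reps`, `n_failed`; per-replicate scores are in
#'   `attr(, "replicates")`.
#' @export
#' @examples
#' run_mixture_experiment(alphas = 0.3, n_reps = 2, n_subclones = 1,
#'                        callers = list(oracle = caller_oracle()),
#'                        seed = 1, n_loci = 900, block_length = 100)
run_mixture_experiment <- function(alphas, n_reps = 200, n_subclones = 1,
                                   callers = list("m-measure" = caller_mmeasure()),
                                   seed = NULL, ...) {
  check_that(is.numeric(alphas) && length(alphas) >= 1 &&
               all(alphas >= 0 & alphas <= 1),
             "`alphas` must be coefficients in [0, 1]")
  check_that(is_count(n_reps), "`n_reps` must be a positive integer")
  check_that(is.list(callers) && length(callers) >= 1 &&
               !is.null(names(callers)) && all(nzchar(names(callers))),
             "`callers` must be a named list of functions")
  maybe_set_seed(seed)
  reps <- expand.grid(rep = seq_len(n_reps), alpha = alphas,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(reps) * length(callers))
  ri <- 0
  for (i in seq_len(nrow(reps))) {
    sim <- simulate_mixture(alpha = reps$alpha[i], n_subclones = n_subclones,
                            ...)
    for (nm in names(callers)) {
      auc <- tryCatch(
        auc_roc_three_class(callers[[nm]](sim$profile, sim$truth), sim$truth),
        error = function(e) NA_real_)
      ri <- ri + 1
      rows[[ri]] <- data.frame(alpha = reps$alpha[i], caller = nm,
                               rep = reps$rep[i], auc = auc)
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_rep,
                                     list(per_rep$alpha, per_rep$caller),
                                     drop = TRUE), function(d) {
    data.frame(alpha = d$alpha[1], caller = d$caller[1],
               mean_auc = mean(d$auc, na.rm = TRUE),
               sd_auc = stats::sd(d$auc, na.rm = TRUE),
               n_reps = nrow(d), n_failed = sum(is.na(d$auc)))
  }))
  agg <- agg[order(agg$caller, agg$alpha), ]
  rownames(agg) <- NULL
  attr(agg, "replicates") <- per_rep
  agg
}
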