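HMM_STATES <- c("normal", "loss", "gain")

#' Parameters of the three-state segmentation HMM (3SMM)
#'
#' The hidden states are `normal`, `loss` (deletion segment) and `gain`
#' (duplication segment); the per-SNP observation is the pair (M-measure,
#' windowed mean log-R), modeled per state as independent Gaussians.
#'
#' @param transition 3x3 row-stochastic matrix with rows/columns ordered
#'   `normal`, `loss`, `gain`.
#' @param emission Named list with one entry per state, each a list with
#'   `m_mean`, `m_sd`, `logr_mean`, `logr_sd` (sds positive).
#' @param initial Optional initial state distribution (default uniform).
#' @return A list of class `"hmm_params"`.
#' @export
hmm_params <- function(transition, emission, initial = rep(1 / 3, 3)) {
  transition <- as.matrix(transition)
  check_that(all(dim(transition) == c(3, 3)),
             "`transition` must be a 3x3 matrix")
  check_that(all(is.finite(transition)) && all(transition >= 0),
             "transition probabilities must be non-negative")
  check_that(all(abs(rowSums(transition) - 1) <= 1e-8),
             "transition rows must sum to 1")
  check_that(is.list(emission) && all(HMM_STATES %in% names(emission)),
             "`emission` must name all of normal, loss, gain")
  for (s in HMM_STATES) {
    e <- emission[[s]]
    check_that(all(c("m_mean", "m_sd", "logr_mean", "logr_sd") %in% names(e)),
               "each emission entry needs m_mean, m_sd, logr_mean, logr_sd")
    check_that(e$m_sd > 0 && e$logr_sd > 0, "emission sds must be positive")
  }
  check_that(length(initial) == 3 && all(initial >= 0) &&
               abs(sum(initial) - 1) <= 1e-8,
             "`initial` must be a length-3 distribution")
  dimnames(transition) <- list(HMM_STATES, HMM_STATES)
  structure(list(transition = transition, emission = emission[HMM_STATES],
                 initial = as.numeric(initial)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Three-state segmentation HMM parameters\n")
  print(round(x$transition, 4))
  em <- t(vapply(x$emission, function(e)
    c(m_mean = e$m_mean, m_sd = e$m_sd,
      logr_mean = e$logr_mean, logr_sd = e$logr_sd), numeric(4)))
  print(round(em, 4))
  invisible(x)
}

#' Generic Viterbi decoding over per-state log-likelihoods
#'
#' Computes the maximum-a-posteriori state path for arbitrary per-observation
#' state log-likelihoods. Ties are broken toward the first state (the state
#' ordering puts `normal` first), both in the running maximisation and in the
#' final state choice, so decoding is deterministic.
#'
#' @param loglik A T x S matrix of per-observation, per-state
#'   log-likelihoods.
#' @param transition S x S row-stochastic transition matrix.
#' @param initial Initial state distribution (default uniform).
#' @return Integer vector of decoded state indices (length T), with the path
#'   log-probability in `attr(, "logp")`.
#' @export
viterbi_decode <- function(loglik, transition,
                           initial = rep(1 / nrow(transition),
                                         nrow(transition))) {
  loglik <- as.matrix(loglik)
  transition <- as.matrix(transition)
  n_states <- nrow(transition)
  check_that(ncol(transition) == n_states, "`transition` must be square")
  check_that(all(is.finite(transition)) && all(transition >= 0),
             "transition probabilities must be non-negative")
  check_that(all(abs(rowSums(transition) - 1) <= 1e-8),
             "transition rows must sum to 1")
  check_that(ncol(loglik) == n_states,
             "`loglik` must have one column per state")
  tt <- nrow(loglik)
  check_that(tt >= 1, "at least one observation is required")
  log_trans <- log(transition)
  delta <- matrix(-Inf, tt, n_states)
  psi <- matrix(1L, tt, n_states)
  delta[1, ] <- log(initial) + loglik[1, ]
  if (tt > 1) {
    for (t in 2:tt) {
      for (s in seq_len(n_states)) {
        cand <- delta[t - 1, ] + log_trans[, s]
        best <- which.max(cand)  # first maximum: ties toward state 1
        psi[t, s] <- best
        delta[t, s] <- cand[best] + loglik[t, s]
      }
    }
  }
  path <- integer(tt)
  path[tt] <- which.max(delta[tt, ])
  if (tt > 1) {
    for (t in (tt - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  }
  structure(path, logp = max(delta[tt, ]))
}

hmm_loglik <- function(m, logr_mean, params) {
  vapply(HMM_STATES, function(s) {
    e <- params$emission[[s]]
    stats::dnorm(m, e$m_mean, e$m_sd, log = TRUE) +
      stats::dnorm(logr_mean, e$logr_mean, e$logr_sd, log = TRUE)
  }, numeric(length(m)))
}

#' Three-state Viterbi segmentation over M-measure and log-R observations
#'
#' Decodes the maximum-a-posteriori sequence of `normal` / `loss` / `gain`
#' segments under the three-state HMM whose per-SNP observations are the
#' M-measure and the windowed mean log-R (the 3SMM decoder). Ties are broken
#' toward `normal`.
#'
#' @inheritParams classify_cna
#' @param params An [hmm_params()] object, typically from
#'   [fit_hmm_from_truth()].
#' @return A `"cna_calls"` object (method `"3smm"`).
#' @export
viterbi_3smm <- function(profile, params, window = 20,
                         imbalance_fn = imbalance_sin2, hom_delta = 0.1,
                         rho_floor = 2^-10) {
  profile <- as_profile_df(profile)
  check_that(inherits(params, "hmm_params"), "`params` must be hmm_params")
  obs <- smm_observations(profile, window, imbalance_fn, hom_delta, rho_floor)
  ll <- hmm_loglik(obs$m, obs$logr_mean, params)
  if (nrow(profile) == 1) ll <- matrix(ll, nrow = 1)
  path <- viterbi_decode(ll, params$transition, params$initial)
  new_cna_calls(profile, state = HMM_STATES[path], m = obs$m,
                logr_mean = obs$logr_mean, method = "3smm",
                config = list(window = window, hom_delta = hom_delta,
                              rho_floor = rho_floor))
}

smm_observations <- function(profile, window, imbalance_fn, hom_delta,
                             rho_floor) {
  n <- nrow(profile)
  m <- m_measure(profile, window = window, imbalance_fn = imbalance_fn,
                 hom_delta = hom_delta)
  logr_eff <- profile$log_r
  if (is.null(logr_eff)) logr_eff <- rep(NA_real_, n)
  bad <- !is.finite(logr_eff)
  if (any(bad)) {
    rho <- if (is.null(profile$rho)) rep(0, n) else profile$rho
    logr_eff[bad] <- log2(pmax(rho[bad], rho_floor))
  }
  hw <- window_halfwidths(n, min(window, n))
  list(m = m, logr_mean = window_sum(logr_eff, hw) / (2 * hw + 1))
}

#' Fit 3SMM parameters from the simulated truth
#'
#' Estimates the transition matrix from the empirical state bigrams of the
#' true per-locus labels (with add-one smoothing) and the per-state Gaussian
#' emission parameters from the observed (M-measure, windowed mean log-R)
#' pairs of the loci carrying each true label. Emission standard deviations
#' are floored at `sd_floor` so degenerate (constant) observations remain
#' decodable.
#'
#' @inheritParams viterbi_3smm
#' @param truth Factor or character vector of true per-locus states
#'   (`gain` / `loss` / `normal`), or a `cna_sim` whose truth is used.
#' @param sd_floor Lower bound on emission standard deviations
#'   (default 1e-4).
#' @return An [hmm_params()] object.
#' @export
fit_hmm_from_truth <- function(profile, truth, window = 20,
                               imbalance_fn = imbalance_sin2,
                               hom_delta = 0.1, rho_floor = 2^-10,
                               sd_floor = 1e-4) {
  if (inherits(profile, "cna_sim") && missing(truth)) truth <- profile$truth
  if (inherits(truth, "cna_sim")) truth <- truth$truth
  profile <- as_profile_df(profile)
  truth <- state_factor(as.character(truth))
  check_that(length(truth) == nrow(profile),
             "`truth` must be aligned with the profile")
  check_that(!anyNA(truth), "truth labels must be gain, loss or normal")
  missing_states <- setdiff(HMM_STATES, as.character(unique(truth)))
  if (length(missing_states) > 0) {
    stop("state(s) ", paste(missing_states, collapse = ", "),
         " absent from the truth track; supply hmm_params() built from ",
         "defaults or from a dataset containing all three states",
         call. = FALSE)
  }
  obs <- smm_observations(profile, window, imbalance_fn, hom_delta, rho_floor)
  tr_lab <- as.character(truth)
  counts <- matrix(1, 3, 3, dimnames = list(HMM_STATES, HMM_STATES))
  n <- length(tr_lab)
  if (n > 1) {
    bigrams <- table(factor(tr_lab[-n], HMM_STATES),
                     factor(tr_lab[-1], HMM_STATES))
    counts <- counts + unclass(bigrams)
  }
  transition <- counts / rowSums(counts)
  emission <- lapply(HMM_STATES, function(s) {
    sel <- tr_lab == s
    list(m_mean = mean(obs$m[sel]),
         m_sd = max(stats::sd(obs$m[sel]), sd_floor, na.rm = TRUE),
         logr_mean = mean(obs$logr_mean[sel]),
         logr_sd = max(stats::sd(obs$logr_mean[sel]), sd_floor, na.rm = TRUE))
  })
  names(emission) <- HMM_STATES
  initial <- as.numeric(table(truth)[HMM_STATES] / n)
  hmm_params(transition, emission, initial)
}
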