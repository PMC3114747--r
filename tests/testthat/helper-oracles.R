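# Independent oracles used across tests: naive loop-based implementations
# kept deliberately separate from the package's vectorized code paths.

# naive weighted sum of component copy vectors
oracle_mix <- function(components, coefficients) {
  n <- length(components[[1]]$a)
  a <- numeric(n)
  b <- numeric(n)
  for (j in seq_len(n)) {
    for (i in seq_along(components)) {
      a[j] <- a[j] + coefficients[i] * components[[i]]$a[j]
      b[j] <- b[j] + coefficients[i] * components[[i]]$b[j]
    }
  }
  list(a = a, b = b)
}

# per-class balanced accuracy by explicit tallying
oracle_three_class_auc <- function(calls, truth) {
  calls <- as.character(calls)
  truth <- as.character(truth)
  total <- 0
  for (cl in c("gain", "loss", "normal")) {
    tp <- 0; p <- 0; tn <- 0; n <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl) {
        p <- p + 1
        if (calls[i] == cl) tp <- tp + 1
      } else {
        n <- n + 1
        if (calls[i] != cl) tn <- tn + 1
      }
    }
    tpr <- if (p == 0) 1 else tp / p
    tnr <- if (n == 0) 1 else tn / n
    total <- total + (tpr + tnr) / 2
  }
  total / 3
}

# exhaustive maximum over all state paths
oracle_viterbi <- function(loglik, transition, initial) {
  n_states <- nrow(transition)
  tt <- nrow(loglik)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n_states)), tt)))
  lp <- apply(paths, 1, function(p) {
    v <- log(initial[p[1]]) + loglik[1, p[1]]
    if (tt > 1) {
      for (t in 2:tt) {
        v <- v + log(transition[p[t - 1], p[t]]) + loglik[t, p[t]]
      }
    }
    v
  })
  best <- max(lp)
  list(logp = best,
       optimal = paths[lp >= best - 1e-9, , drop = FALSE])
}

# Clopper-Pearson interval from the beta-quantile closed form
oracle_clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

# small simulated dataset for fast module tests (500 loci, 50-locus blocks)
small_sim <- function(alpha = 0.3, n_subclones = 1, snr = 30, seed = 1,
                      n_loci = 500, block_length = 50) {
  simulate_mixture(alpha = alpha, n_subclones = n_subclones, snr = snr,
                   n_loci = n_loci, block_length = block_length, seed = seed)
}
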