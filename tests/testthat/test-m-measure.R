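test_that("M-measure vanishes at the normal-state BAF values", {
  n <- 40
  # balanced heterozygotes
  expect_equal(m_measure(locus_profile(beta = rep(0.5, n), rho = rep(1, n))),
               rep(0, n))
  # homozygous loci carry no imbalance information
  expect_equal(m_measure(locus_profile(beta = rep(c(0, 1), n / 2),
                                       rho = rep(1, n))),
               rep(0, n))
  # constant window at beta 0.25 scores the per-SNP maximum f(0.25) = 1
  m <- m_measure(locus_profile(beta = rep(0.25, n), rho = rep(1, n)))
  expect_equal(m, rep(1, n))
  expect_gt(m[1], 0.1)  # clearly above the default aberrance cutoff
})

test_that("M-measure is symmetric under allele relabeling", {
  set.seed(31)
  beta <- stats::runif(200)
  p1 <- locus_profile(beta = beta, rho = rep(1, 200))
  p2 <- locus_profile(beta = 1 - beta, rho = rep(1, 200))
  expect_equal(m_measure(p1), m_measure(p2), tolerance = 1e-12)
})

test_that("M-measure grows as balanced SNPs move to an imbalanced value", {
  n <- 21
  prev <- -1
  for (k in seq(0, n)) {
    beta <- c(rep(0.25, k), rep(0.5, n - k))
    m <- m_measure(locus_profile(beta = beta, rho = rep(1, n)), window = n)
    expect_gte(m[11], prev)
    prev <- m[11]
  }
  expect_equal(prev, 1)
})

test_that("aberrant-block M approaches normal-block M as tumor fraction vanishes", {
  m_on_blocks <- function(alpha) {
    sim <- simulate_mixture(alpha = alpha, n_subclones = 1, n_loci = 2000,
                            block_length = 200, seed = 77)
    m <- m_measure(sim$profile)
    gain <- which(sim$truth == "gain")
    normal <- which(sim$truth == "normal")
    c(mean(m[gain]), mean(m[normal]))
  }
  strong <- m_on_blocks(0.2)
  weak <- m_on_blocks(0.95)
  # contrast between aberrant and normal blocks collapses with the signal
  expect_gt(strong[1] - strong[2], 5 * (weak[1] - weak[2]))
})

test_that("classifier is quiet on pure normal data and labels simulated blocks", {
  # noiseless pure stroma: every SNP normal
  pure <- small_sim(alpha = 1, snr = Inf, seed = 13)
  expect_true(all(classify_cna(pure)$state == "normal"))

  # alpha = 0.3 binary mixture: gain block called gain, flanks normal,
  # allowing a window-width boundary smear
  sim <- simulate_mixture(alpha = 0.3, n_subclones = 1, seed = 14)
  fit <- classify_cna(sim)
  gain1 <- which(vapply(sim$truth_specs[[1]], function(s) s$kind == "gain_one",
                        logical(1)))
  s <- sim$truth_specs[[1]][[gain1]]
  core <- (s$start_locus + 1):(s$start_locus + s$length)
  expect_gt(mean(fit$state[core] == "gain"), 0.9)
  flank <- setdiff(which(sim$truth == "normal"), core)
  expect_gt(mean(fit$state[flank] == "normal"), 0.95)
})

test_that("majority hemizygous deletions blind to M are rescued by the rho test", {
  # nearly pure tumor: het BAF collapses onto the homozygous bands, so the
  # M-measure is silent, but rho = 0.525 fires the depressed-log-R test
  sim <- simulate_mixture(alpha = 0.05, n_subclones = 1, snr = Inf, seed = 15)
  fit <- classify_cna(sim)
  hemi <- which(vapply(sim$truth_specs[[1]], function(s)
    s$kind == "hemizygous_deletion", logical(1)))
  s <- sim$truth_specs[[1]][[hemi]]
  idx <- (s$start_locus + 1):(s$start_locus + s$length)
  expect_lt(mean(fit$m[idx]), attr(fit, "config")$m_cutoff)
  expect_true(all(fit$state[idx] == "loss"))
})

test_that("classifier validates its inputs", {
  prof <- locus_profile(beta = rep(0.5, 10), rho = rep(1, 10))
  expect_error(m_measure(prof, window = 11), "must not exceed")
  expect_error(m_measure(prof, window = 0), "positive integer")
  expect_error(classify_cna(prof, m_cutoff = 0), "\\(0, 1\\)")
  expect_error(classify_cna(data.frame(x = 1)), "beta")
})

test_that("call objects expose methods of a fitted model", {
  sim <- small_sim(alpha = 0.3, seed = 16)
  fit <- classify_cna(sim)
  expect_s3_class(fit, "cna_calls")
  expect_output(print(fit), "Three-state CNA calls")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.cna_calls")
  expect_output(print(sm), "segments")
  df <- as.data.frame(fit)
  expect_false(inherits(df, "cna_calls"))
  expect_true(all(c("m", "log_r_mean", "state") %in% names(df)))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
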