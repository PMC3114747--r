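test_that("candidate formulas follow the closed form x = (c - m) / (2 - m)", {
  # noiseless: c = 1.3 at hemizygous and c = 0.6 at homozygous deletion loci
  prof <- locus_profile(beta = rep(0, 4), rho = c(1.3, 1.3, 0.6, 0.6) / 2)
  fit <- infer_mixing_coefficient(prof, 1:4)
  expect_equal(fit$candidates$cand_m0, c(0.65, 0.65, 0.3, 0.3))
  expect_equal(fit$candidates$cand_m1, c(0.3, 0.3, -0.4, -0.4))
  expect_equal(coef(fit), c(x = 0.3))
  expect_equal(fit$per_locus_m, c(1L, 1L, 0L, 0L))

  # pure tumor with homozygous deletion: c = 0 gives x = 0, m = 0
  prof0 <- locus_profile(beta = rep(0.5, 2), rho = c(0, 0))
  fit0 <- infer_mixing_coefficient(prof0, 1:2)
  expect_equal(coef(fit0), c(x = 0))
  expect_equal(fit0$per_locus_m, c(0L, 0L))

  # generic closed-form property on random deletion signals
  set.seed(8)
  c_bar <- stats::runif(30, 0, 2)
  fitr <- infer_mixing_coefficient(
    locus_profile(beta = rep(0, 30), rho = c_bar / 2), 1:30)
  expect_equal(fitr$candidates$cand_m0, (fitr$candidates$c_bar - 0) / 2)
  expect_equal(fitr$candidates$cand_m1, (fitr$candidates$c_bar - 1) / 1)
})

test_that("deletion-locus preconditions are enforced", {
  prof <- locus_profile(beta = rep(0.5, 5), rho = rep(1.2, 5))
  expect_error(infer_mixing_coefficient(prof, 1:5), "no deletion loci")
  expect_error(infer_mixing_coefficient(prof, integer(0)), "non-empty")
  expect_error(infer_mixing_coefficient(prof, 99), "out of range")
})

test_that("mixing coefficient is recovered from noiseless simulations on a 0.05 grid", {
  for (alpha in seq(0.05, 0.95, by = 0.05)) {
    sim <- simulate_mixture(alpha = alpha, n_subclones = 1, snr = Inf,
                            n_loci = 2000, block_length = 200, seed = 41)
    # truth deletion loci: both deletion kinds represented at every alpha
    x <- coef(infer_mixing_coefficient(sim$profile,
                                       which(sim$truth == "loss")))
    expect_lt(abs(x - alpha), 0.011)  # within one histogram bin
    # classifier-driven loci behave the same while both deletion kinds
    # survive the log-R tolerance band
    if (alpha <= 0.85) {
      fit <- classify_cna(sim)
      xc <- coef(infer_mixing_coefficient(sim$profile,
                                          which(fit$state == "loss")))
      expect_lt(abs(xc - alpha), 0.011)
    }
  }
})

test_that("enumeration validates its guard and grid", {
  agg <- allele_signal(rep(1, 13), rep(1, 13))
  expect_error(enumerate_demixings(agg, k = 2), "guard")
  expect_error(enumerate_demixings(allele_signal(1, 1), k = 5), "guard")
  expect_error(enumerate_demixings(allele_signal(1, 1), k = 1,
                                   coefficient_grid = 0.3), "divide 1")
})

test_that("a binary aggregate is its own unique single-component de-mixing", {
  agg <- allele_signal(c(1, 0, 1), c(0, 1, 1))
  res <- enumerate_demixings(agg, k = 1)
  expect_equal(res$n_solutions, 1)
  expect_equal(res$search_space_size, 7)
  expect_equal(res$solutions[[1]]$components[[1]]$a, c(1, 0, 1))
})

test_that("two independent components de-mix uniquely; three do not", {
  # two components, two independent measurements
  g1 <- subclone_genome(c(1, 0), c(0, 1))
  g2 <- subclone_genome(c(1, 1), c(1, 0))
  agg2 <- mix_signals(list(g1, g2), c(0.4, 0.6))
  res2 <- enumerate_demixings(agg2, k = 2, coefficient_grid = 0.1)
  expect_equal(res2$n_solutions, 1)

  # three components over three loci: multiple exact reconstructions
  h1 <- subclone_genome(c(1, 0, 0), c(0, 1, 1))
  h2 <- subclone_genome(c(1, 1, 0), c(1, 0, 1))
  h3 <- subclone_genome(c(0, 1, 1), c(1, 1, 0))
  agg3 <- mix_signals(list(h1, h2, h3), c(0.5, 0.3, 0.2))
  res3 <- enumerate_demixings(agg3, k = 3, coefficient_grid = 0.1)
  expect_gte(res3$n_solutions, 2)

  # every returned solution re-mixes to the aggregate exactly
  cases <- list(list(res = res2, agg = agg2), list(res = res3, agg = agg3))
  for (case in cases) {
    for (sol in case$res$solutions) {
      comps <- lapply(sol$components, function(cc)
        subclone_genome(cc$a, cc$b))
      remixed <- mix_signals(comps, sol$coefficients)
      expect_equal(remixed$a, case$agg$a, tolerance = 1e-12)
      expect_equal(remixed$b, case$agg$b, tolerance = 1e-12)
    }
  }
})
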