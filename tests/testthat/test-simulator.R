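test_that("germline generation matches the heterozygosity model", {
  g0 <- generate_germline(200, het_prob = 0, seed = 1)
  expect_true(all(g0$h1 == g0$h2))
  g1 <- generate_germline(200, het_prob = 1, seed = 1)
  expect_true(all(g1$h1 != g1$h2))

  g <- generate_germline(10000, het_prob = 0.095, seed = 11)
  expect_true(all(g$h1 %in% 0:1) && all(g$h2 %in% 0:1))
  expect_equal(g$het, g$h1 != g$h2)
  # binomial 3-sigma band around 9.5%
  se3 <- 3 * sqrt(0.095 * 0.905 / 10000)
  expect_lt(abs(mean(g$het) - 0.095), se3)
  # homozygous loci split roughly evenly between AA and BB
  hom_b <- mean(g$h1[!g$het] == 1)
  expect_lt(abs(hom_b - 0.5), 3 * sqrt(0.25 / sum(!g$het)))
})

test_that("aberrations edit haplotype copies as specified", {
  g <- generate_germline(100, het_prob = 1, seed = 2)  # all het: A/B at each locus

  none <- apply_aberrations(g, list())
  expect_equal(none$a_copies + none$b_copies, rep(2L, 100))

  gain <- apply_aberrations(g, list(aberration_spec("gain_one", 10, 20)),
                            seed = 3)
  idx <- 11:30
  tot <- gain$a_copies + gain$b_copies
  expect_true(all(tot[idx] == 3))
  expect_true(all(tot[-idx] == 2))
  # one parental haplotype duplicated: copies are (2,1) or (1,2) at het loci
  expect_true(all(gain$a_copies[idx] %in% 1:2))

  hemi <- apply_aberrations(g, list(aberration_spec("hemizygous_deletion", 0, 50)))
  expect_true(all((hemi$a_copies + hemi$b_copies)[1:50] == 1))
  expect_true(all((hemi$a_copies + hemi$b_copies)[51:100] == 2))

  hom <- apply_aberrations(g, list(aberration_spec("homozygous_deletion", 5, 5)))
  expect_true(all(hom$a_copies[6:10] == 0 & hom$b_copies[6:10] == 0))

  expect_error(apply_aberrations(g, list(aberration_spec("gain_one", 0, 30),
                                         aberration_spec("gain_two", 20, 30))),
               "must not overlap")
})

test_that("simulated datasets honor the forward model and the truth rule", {
  # pure stroma: all-normal truth, rho centered on 1, balanced het band
  pure <- small_sim(alpha = 1, seed = 5)
  expect_true(all(pure$truth == "normal"))
  expect_lt(abs(mean(pure$profile$rho) - 1), 0.02)
  het_beta <- pure$profile$beta[pure$germline$het]
  expect_lt(abs(mean(het_beta) - 0.5), 0.02)

  # pure tumor, noiseless: hemizygous-deletion block has rho 0.5 and
  # beta in {0,1} at germline-het loci
  noiseless <- small_sim(alpha = 0, snr = Inf, seed = 6)
  hemi <- which(vapply(noiseless$truth_specs[[1]], function(s)
    s$kind == "hemizygous_deletion", logical(1)))
  s <- noiseless$truth_specs[[1]][[hemi]]
  idx <- (s$start_locus + 1):(s$start_locus + s$length)
  expect_equal(noiseless$profile$rho[idx], rep(0.5, length(idx)))
  het_idx <- idx[noiseless$germline$het[idx]]
  expect_true(all(noiseless$profile$beta[het_idx] %in% c(0, 1)))

  # 70:30 stroma/tumor, noiseless: rho = 0.85 on the hemizygous block
  mix <- small_sim(alpha = 0.7, snr = Inf, seed = 6)
  expect_equal(mix$profile$rho[idx], rep(0.85, length(idx)))

  # noiseless aggregate copy number is the weighted component sum exactly
  agg <- mix_signals(mix$components, mix$coefficients)
  expect_equal(2 * mix$profile$rho, agg$a + agg$b, tolerance = 1e-12)
})

test_that("truth labels follow the dominant aberrant component", {
  sim <- small_sim(alpha = 0.4, n_subclones = 2, seed = 9)
  # subclone 1 has the larger coefficient: wherever it is aberrant the
  # label must match its aberration sign
  lab <- as.character(sim$truth)
  for (s in sim$truth_specs[[1]]) {
    idx <- (s$start_locus + 1):(s$start_locus + s$length)
    expected <- if (s$kind %in% c("gain_one", "gain_two")) "gain" else "loss"
    expect_true(all(lab[idx] == expected))
  }
  # loci covered by no aberration are normal
  covered <- logical(sim$n_loci)
  for (specs in sim$truth_specs) {
    for (s in specs) {
      covered[(s$start_locus + 1):(s$start_locus + s$length)] <- TRUE
    }
  }
  expect_true(all(lab[!covered] == "normal"))
})

test_that("identical seeds reproduce the dataset bit for bit", {
  s1 <- small_sim(alpha = 0.35, n_subclones = 2, seed = 123)
  s2 <- small_sim(alpha = 0.35, n_subclones = 2, seed = 123)
  expect_identical(s1$profile$beta, s2$profile$beta)
  expect_identical(s1$profile$log_r, s2$profile$log_r)
  expect_identical(s1$truth, s2$truth)
  s3 <- small_sim(alpha = 0.35, n_subclones = 2, seed = 124)
  expect_false(identical(s1$profile$beta, s3$profile$beta))
})

test_that("layout validation rejects too-small locus counts", {
  expect_error(simulate_mixture(alpha = 0.5, n_loci = 300, block_length = 50),
               "block layout")
  expect_error(simulate_mixture(alpha = 2), "\\[0, 1\\]")
})
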