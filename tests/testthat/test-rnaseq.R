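test_that("imbalance score follows the folded alt-fraction formula", {
  sites <- data.frame(transcript_id = "TX1", pos = c(10, 20, 30),
                      ref_count = c(100, 100, 150),
                      alt_count = c(100, 0, 50))
  sc <- score_sites(sites, min_reads = 100)
  expect_equal(sc$score, c(0.5, 0, 0.25))
  # symmetry under swapping ref and alt counts
  swapped <- score_sites(data.frame(transcript_id = "TX1", pos = c(10, 20, 30),
                                    ref_count = c(100, 0, 50),
                                    alt_count = c(100, 100, 150)),
                         min_reads = 100)
  expect_equal(swapped$score, sc$score)
})

test_that("coverage filter and Clopper-Pearson intervals are exact", {
  sites <- data.frame(transcript_id = "TX1", pos = 1:3,
                      ref_count = c(60, 150, 40), alt_count = c(39, 50, 20))
  sc <- score_sites(sites, min_reads = 100)
  expect_equal(sc$pos, 2)  # 99 and 60 reads are discarded
  expect_equal(c(sc$ci_low, sc$ci_high),
               oracle_clopper_pearson(50, 200), tolerance = 1e-12)
  # masked rows (e.g. indel-adjacent) are honored
  sites$mask <- c(FALSE, TRUE, FALSE)
  expect_equal(nrow(score_sites(sites, min_reads = 100)), 0)
})

test_that("within-exon CI-disjoint pairs are called, across-exon pairs are not", {
  exons <- data.frame(transcript_id = "TX1", start = c(0, 200),
                      end = c(200, 400))
  sites <- data.frame(transcript_id = "TX1", pos = c(50, 90, 250),
                      ref_count = c(100, 190, 100),
                      alt_count = c(100, 10, 100))
  sc <- score_sites(sites, min_reads = 100)
  calls <- detect_exon_fluctuation(sc, exons)
  # 100/200 vs 10/200 within exon 1: CIs (0.429,0.571) vs (0.024,0.090)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$pos1, calls$pos2), c(50, 90))
  expect_true(calls$within_read_length)
  expect_true(calls$adjacent)

  # identical sites yield no call
  same <- score_sites(data.frame(transcript_id = "TX1", pos = c(50, 90),
                                 ref_count = c(100, 100),
                                 alt_count = c(100, 100)), 100)
  expect_equal(nrow(detect_exon_fluctuation(same, exons)), 0)

  # sites outside every exon are skipped with a warning
  stray <- score_sites(data.frame(transcript_id = "TX1", pos = c(50, 90, 999),
                                  ref_count = c(100, 190, 100),
                                  alt_count = c(100, 10, 100)), 100)
  expect_warning(calls2 <- detect_exon_fluctuation(stray, exons), "outside")
  expect_equal(nrow(calls2), 1)
})

test_that("Fisher mode applies BH correction over all pairs", {
  exons <- data.frame(transcript_id = "TX1", start = 0, end = 400)
  sites <- data.frame(transcript_id = "TX1", pos = c(10, 60, 120),
                      ref_count = c(100, 103, 190),
                      alt_count = c(100, 97, 10))
  sc <- score_sites(sites, 100)
  calls <- detect_exon_fluctuation(sc, exons, method = "fisher")
  expect_true(all(c("p_value", "q_value") %in% names(calls)))
  expect_equal(nrow(calls), 2)  # the two pairs against the imbalanced site
  expect_true(all(calls$q_value < 0.05))
})

test_that("fixtures plant the subclone-mixture allele probabilities", {
  fx <- generate_rnaseq_fixture(rep(1 / 3, 3),
                                somatic_pos = c(120, 180),
                                somatic_carriers = list(1, c(2, 3)),
                                germline_pos = 60, depth = 1000, seed = 4)
  expect_equal(fx$true_alt_prob, c(0.5, 1 / 3, 2 / 3))
  expect_equal(fx$ref_count + fx$alt_count, rep(1000L, 3))
  # variant carried by every subclone saturates the alt fraction
  full <- generate_rnaseq_fixture(c(0.6, 0.4), somatic_pos = 5,
                                  somatic_carriers = list(1:2),
                                  depth = 1000, seed = 5)
  expect_equal(full$true_alt_prob, 1)
  expect_equal(full$alt_count, 1000L)
  expect_error(generate_rnaseq_fixture(c(0.5, 0.4), somatic_pos = 1,
                                       somatic_carriers = list(1)),
               "sum to 1")
  expect_error(generate_rnaseq_fixture(c(0.5, 0.5), somatic_pos = 1,
                                       somatic_carriers = list(3)),
               "existing subclones")
})

test_that("planted subclone fractions are covered by the site CIs at depth 500", {
  hits <- 0
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    fx <- generate_rnaseq_fixture(c(0.5, 0.3, 0.2), somatic_pos = 10,
                                  somatic_carriers = list(c(1, 3)),
                                  depth = 500, seed = 1000 + s)
    sc <- score_sites(fx, min_reads = 100)
    hits <- hits + (sc$ci_low <= 0.7 && 0.7 <= sc$ci_high)
  }
  expect_gte(hits / n_rep, 0.93)
})
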