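# PWM construction, exact threshold calibration and both-strand scanning.

test_that("log-odds weights follow the pseudocount formula", {
  # uniform column is uninformative
  u <- matrix(c(1, 1, 1, 1), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  expect_equal(unname(build_pwm(u, pseudocount = 1)$weights[, 1]), rep(0, 4))

  # hand evaluation: counts (8,0,0,0), uniform bg, pseudocount 1
  m <- matrix(c(8, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  w <- build_pwm(m, pseudocount = 1)$weights
  expect_equal(unname(w["A", 1]), log2(((8 + 0.25) / 9) / 0.25), tolerance = 1e-12)
  expect_equal(unname(w["C", 1]), log2(((0 + 0.25) / 9) / 0.25), tolerance = 1e-12)
  expect_equal(unname(w["A", 1]), 1.8745, tolerance = 1e-4)
  expect_equal(unname(w["C", 1]), -3.1699, tolerance = 1e-4)

  # count scaling matters only through the pseudocount: vanishing pseudocount
  # makes weights of positive counts scale-invariant
  mp <- matrix(c(8, 1, 2, 1), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  w_small <- build_pwm(mp, pseudocount = 1e-9)$weights
  w2_small <- build_pwm(mp * 2, pseudocount = 1e-9)$weights
  expect_equal(w_small, w2_small, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(build_pwm(mp, pseudocount = 1)$weights,
                                build_pwm(mp * 2, pseudocount = 1)$weights)))
})

test_that("invalid count matrices and parameters are rejected", {
  z <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 4, 2, dimnames = list(c("A", "C", "G", "T")))
  expect_error(build_pwm(z), "zero-sum")
  m <- tiny_pcm()
  expect_error(build_pwm(m, pseudocount = 0), "positive")
  expect_error(calibrate_threshold(build_pwm(m), alpha = 0), "alpha")
  expect_error(calibrate_threshold(build_pwm(m), alpha = 1.5), "alpha")
})

test_that("threshold calibration matches enumeration on single columns", {
  m <- matrix(c(8, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  pwm <- build_pwm(m, pseudocount = 1)
  cal <- calibrate_threshold(pwm, alpha = 0.25)
  # only A (weight 1.8745) passes; threshold sits at that weight up to grid error
  expect_equal(cal$threshold, unname(pwm$weights["A", 1]), tolerance = 2e-3)
  expect_equal(cal$attained_p, 0.25)

  # alpha = 1: every word passes, threshold at the minimum achievable score
  cal1 <- calibrate_threshold(pwm, alpha = 1)
  expect_equal(cal1$threshold, pwm_min_score(pwm), tolerance = 2e-3)
  expect_equal(cal1$attained_p, 1)
  expect_equal(nrow(scan_sequence(cal1, "ACGTTGCA", both_strands = FALSE)), 8L)
})

test_that("DP score distribution equals exhaustive enumeration", {
  set.seed(11)
  for (bg in list(uniform_background(),
                  c(A = 0.2, C = 0.3, G = 0.3, T = 0.2))) {
    for (L in c(3L, 6L, 8L)) {
      cm <- matrix(rpois(4 * L, 4) + 1, 4, L,
                   dimnames = list(c("A", "C", "G", "T")))
      pwm <- calibrate_threshold(build_pwm(cm, background = bg), alpha = 0.01)
      gran <- pwm$granularity
      p_hi <- enumerate_tail(pwm, bg, pwm$threshold + L * gran)
      p_lo <- enumerate_tail(pwm, bg, pwm$threshold - L * gran)
      expect_lte(p_hi, pwm$attained_p + 1e-12)
      expect_gte(p_lo, pwm$attained_p - 1e-12)
      # the attained p is a genuine tail probability at most alpha
      expect_lte(pwm$attained_p, 0.01)
    }
  }
})

test_that("thresholds are monotone in alpha and hits non-decreasing", {
  pwm <- build_pwm(example_sox9_pcm())
  alphas <- c(1e-5, 1e-4, 1e-3, 1e-2, 0.1, 1)
  thr <- vapply(alphas, function(a) calibrate_threshold(pwm, a)$threshold,
                numeric(1))
  expect_true(all(diff(thr) <= 1e-12))
  s <- random_dna(2000, seed = 5)
  hits <- vapply(alphas, function(a) {
    nrow(scan_sequence(calibrate_threshold(pwm, a), s))
  }, numeric(1))
  expect_true(all(diff(hits) >= 0))
})

test_that("scanning finds planted words on both strands and skips N", {
  pwm <- calibrated_sox9_pwm()
  cons <- consensus_word(pwm)
  s <- paste0(substr(random_dna(60, 3), 1, 7), cons, random_dna(40, 4))
  h <- scan_sequence(pwm, s)
  expect_true(any(h$start == 7 & h$strand == "+"))

  s2 <- paste0(substr(random_dna(60, 5), 1, 3), reverse_complement(cons),
               random_dna(40, 6))
  h2 <- scan_sequence(pwm, s2)
  expect_true(any(h2$start == 3 & h2$strand == "-"))

  expect_equal(nrow(scan_sequence(pwm, strrep("N", 100))), 0L)
  expect_error(scan_sequence(build_pwm(example_sox9_pcm()), "ACGT"),
               "not calibrated")
})

test_that("scanner agrees exactly with the naive per-window oracle", {
  pwm <- calibrated_sox9_pwm(alpha = 5e-3)
  for (seed in 1:8) {
    s <- random_dna(sample(300:600, 1), seed = seed, gc = 0.45)
    expect_equal(scan_sequence(pwm, s), naive_scan(pwm, s))
  }
})

test_that("strand symmetry: hits reflect onto the reverse complement", {
  pwm <- calibrated_sox9_pwm(alpha = 5e-3)
  for (seed in 21:25) {
    s <- random_dna(400, seed = seed)
    h <- scan_sequence(pwm, s)
    h_rc <- scan_sequence(pwm, reverse_complement(s))
    n <- nchar(s); L <- pwm$length
    reflected <- data.frame(start = n - L - h_rc$start,
                            strand = ifelse(h_rc$strand == "+", "-", "+"),
                            score = h_rc$score)
    reflected <- reflected[order(reflected$start, reflected$strand == "-"), ]
    expect_equal(h$start, reflected$start)
    expect_equal(h$strand, reflected$strand)
    expect_equal(h$score, reflected$score)
  }
})

test_that("peaks_with_motif matches per-peak scanning and validates bounds", {
  sim <- small_genome_with_peaks(seed = 31)
  pwm <- calibrated_sox9_pwm(alpha = 1e-3)
  res <- peaks_with_motif(sim$peaks, sim$genome, pwm)
  # batch flags equal a per-peak scan loop
  loop_flags <- vapply(seq_len(nrow(sim$peaks)), function(i) {
    s <- get_seq(sim$genome, sim$peaks$contig[i], sim$peaks$start[i],
                 sim$peaks$end[i])
    nrow(scan_sequence(pwm, s)) > 0L
  }, logical(1))
  expect_equal(unname(res$flags), loop_flags)
  expect_equal(res$n_with_motif, sum(loop_flags))

  empty <- peaks_with_motif(sim$peaks[0, ], sim$genome, pwm)
  expect_equal(empty$n_with_motif, 0L)

  bad <- data.frame(contig = "chr1", start = 49990L, end = 50100L, name = "oops")
  expect_error(peaks_with_motif(bad, sim$genome, pwm), "oops")
})

test_that("planted fixture peaks are flagged exactly", {
  g <- genome_sequence(c(chr1 = random_dna(3000, seed = 41)))
  pwm <- calibrated_sox9_pwm()
  cons <- consensus_word(pwm)
  # scrub then plant into peaks 1 and 3 of three 200 bp peaks
  peaks <- data.frame(contig = "chr1", start = c(100L, 1000L, 2000L),
                      end = c(300L, 1200L, 2200L),
                      name = c("p1", "p2", "p3"))
  for (pos in c(150L, 2050L)) {
    substr(g$contigs[["chr1"]], pos + 1L, pos + nchar(cons)) <- cons
  }
  res <- peaks_with_motif(peaks, g, pwm)
  expect_equal(unname(res$flags), c(TRUE, FALSE, TRUE))
  expect_equal(res$n_with_motif, 2L)
})
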