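# Background sampling and the permutation enrichment statistic.

test_that("a region as long as the contig has a forced placement", {
  g <- generate_genome(1000, gc = 0.5, seed = 1)
  sets <- sample_background_regions(g, 1000L, n_perm = 5, seed = 9)
  for (s in sets) {
    expect_equal(s$start, 0L)
    expect_equal(s$end, 1000L)
  }
  expect_error(sample_background_regions(g, 1001L, n_perm = 1, seed = 9),
               "placeable")
})

test_that("background sampling is deterministic given the seed", {
  g <- generate_genome(20000, gc = 0.4, seed = 2)
  a <- sample_background_regions(g, rep(150L, 40), n_perm = 10, seed = 123)
  b <- sample_background_regions(g, rep(150L, 40), n_perm = 10, seed = 123)
  expect_identical(a, b)
  c <- sample_background_regions(g, rep(150L, 40), n_perm = 10, seed = 124)
  expect_false(identical(a, c))
})

test_that("sampled regions reproduce genome GC on average", {
  g <- generate_genome(2e5, gc = 0.41, seed = 3)
  sets <- sample_background_regions(g, rep(200L, 100), n_perm = 30, seed = 4)
  gc_cs <- peakmotifs:::build_gc_cumsum(g)
  gcs <- unlist(lapply(sets, function(s) {
    peakmotifs:::region_gc(s$contig, s$start, s$end, gc_cs)
  }))
  # 3000 regions of 200 bp: binomial MC error on the mean ~ 6e-4
  expect_equal(mean(gcs), genome_gc(g), tolerance = 0.01)
})

test_that("exclusion intervals are avoided and GC matching honoured", {
  g <- generate_genome(5e4, gc = 0.5, seed = 5)
  excl <- data.frame(contig = "chr1", start = 0L, end = 40000L)
  sets <- sample_background_regions(g, rep(100L, 30), n_perm = 5, seed = 6,
                                    exclusions = excl)
  for (s in sets) expect_true(all(s$start >= 40000L))

  gc_cs <- peakmotifs:::build_gc_cumsum(g)
  tgt <- rep(0.5, 20)
  sets2 <- sample_background_regions(g, rep(200L, 20), n_perm = 3, seed = 7,
                                     gc_match = 0.02, gc_targets = tgt)
  for (s in sets2) {
    gcs <- peakmotifs:::region_gc(s$contig, s$start, s$end, gc_cs)
    expect_true(all(abs(gcs - tgt) <= 0.02))
  }
})

test_that("motif_fraction_summary rounds the containment percentage", {
  flags <- c(rep(TRUE, 847), rep(FALSE, 3633 - 847))
  expect_equal(motif_fraction_summary(flags), list(count = 847L, percent = 23L))
  expect_equal(motif_fraction_summary(rep(FALSE, 100)),
               list(count = 0L, percent = 0L))
  expect_equal(motif_fraction_summary(rep(TRUE, 7)),
               list(count = 7L, percent = 100L))
  expect_error(motif_fraction_summary(logical()), "empty")
})

test_that("enrichment results are reproducible and the p never zero", {
  sim <- small_genome_with_peaks(seed = 51)
  pwm <- calibrated_sox9_pwm(alpha = 1e-3)
  a <- motif_enrichment(sim$peaks, sim$genome, pwm, n_perm = 50, seed = 77)
  b <- motif_enrichment(sim$peaks, sim$genome, pwm, n_perm = 50, seed = 77)
  expect_identical(a, b)
  expect_gt(a$empirical_p, 0)
  expect_lte(a$empirical_p, 1)
  expect_equal(a$fold_enrichment, a$observed_count / mean(a$null_counts))
  expect_equal(a$empirical_p,
               (1 + sum(a$null_counts >= a$observed_count)) / 51)
})

test_that("an unenriched observed count of zero gives fold 0 and p near 1", {
  g <- generate_genome(30000, gc = 0.5, seed = 8)
  # one A-free peak: a poly-C block can hold no A-rich consensus hit
  substr(g$contigs[["chr1"]], 1001, 1300) <- strrep("C", 300)
  peaks <- data.frame(contig = "chr1", start = 1000L, end = 1300L, name = "p")
  pwm <- calibrated_tiny_pwm(alpha = 0.02)
  er <- motif_enrichment(peaks, g, pwm, n_perm = 99, seed = 10)
  expect_equal(er$observed_count, 0)
  if (mean(er$null_counts) > 0) {
    expect_equal(er$fold_enrichment, 0)
  }
  expect_gte(er$empirical_p, 1 - 1 / (1 + 99))
})

test_that("multi-TF enrichment shares null geometry and ranks planted motif first", {
  g <- generate_genome(1e5, gc = 0.45, seed = 61)
  pk <- generate_peaks(g, 150, length_mean = 250, length_sd = 40, seed = 62)
  bg <- background_from_genome(g)
  sox <- calibrate_threshold(build_pwm(example_sox9_pcm(), background = bg),
                             alpha = 1e-4)
  pl <- plant_motifs(g, pk, sox, target_fold = 3, seed = 63,
                     calibration_n = 2000)
  decoys <- lapply(example_decoy_pcms(), function(m) {
    calibrate_threshold(build_pwm(m, background = bg), alpha = 1e-4)
  })
  motifs <- c(list(SOX9 = sox), decoys)
  tab <- multi_tf_enrichment(pk, pl$genome, motifs, n_perm = 100, seed = 64,
                             exclusions = pk)
  expect_equal(tab$tf[1], "SOX9")

  # single-motif reduction equals the one-TF path
  single <- motif_enrichment(pk, pl$genome, sox, n_perm = 100, seed = 64,
                             exclusions = pk)
  row <- tab[tab$tf == "SOX9", ]
  expect_equal(row$observed, single$observed_count)
  expect_equal(row$fold, single$fold_enrichment)
  expect_equal(row$empirical_p, single$empirical_p)

  # permuting the motif list leaves the table unchanged
  tab2 <- multi_tf_enrichment(pk, pl$genome, rev(motifs), n_perm = 100,
                              seed = 64, exclusions = pk)
  expect_equal(tab, tab2, ignore_attr = TRUE)

  expect_error(multi_tf_enrichment(pk, pl$genome, list(sox, sox), n_perm = 10,
                                   seed = 1), "duplicate")
})

test_that("self-drawn peaks show no enrichment", {
  g <- generate_genome(2e5, gc = 0.41, seed = 71)
  pwm <- calibrated_sox9_pwm(alpha = 1e-3,
                             background = background_from_genome(g))
  folds <- vapply(1:8, function(i) {
    pk <- generate_peaks(g, 150, length_mean = 300, length_sd = 50,
                         seed = 100 + i)
    motif_enrichment(pk, g, pwm, n_perm = 60, seed = 200 + i)$fold_enrichment
  }, numeric(1))
  expect_equal(mean(folds), 1, tolerance = 0.08)
})
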