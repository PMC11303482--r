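# TSS metaprofiles and the promoter-window integration.

test_that("a peak spanning the whole window gives full coverage", {
  genes <- data.frame(gene_id = "g1", contig = "chr1", strand = "+", tss = 5000L)
  peaks <- data.frame(contig = "chr1", start = 4000L, end = 6000L, name = "p")
  pr <- tss_metaprofile(peaks, genes, window = 1000L, n_bins = 50L)
  expect_equal(unname(pr$matrix[1, ]), rep(1, 50))
  expect_true(all(pr$column_means == 1))
})

test_that("no peaks give a zero profile; values stay in [0,1]", {
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "chr1",
                      strand = c("+", "-"), tss = c(5000L, 9000L))
  pr <- tss_metaprofile(data.frame(contig = character(), start = integer(),
                                   end = integer()), genes)
  expect_true(all(pr$matrix == 0))

  sim <- small_genome_with_peaks(seed = 81)
  gm <- generate_gene_models(sim$genome, 20, min_spacing = 1500, seed = 82)
  pr2 <- tss_metaprofile(sim$peaks, gm, contig_lengths = sim$genome)
  expect_true(all(pr2$matrix >= 0 & pr2$matrix <= 1, na.rm = TRUE))
})

test_that("a centred peak yields a symmetric, centre-maximal aggregate", {
  genes <- data.frame(gene_id = "g1", contig = "chr1", strand = "+", tss = 5000L)
  peaks <- data.frame(contig = "chr1", start = 4900L, end = 5100L, name = "p")
  pr <- tss_metaprofile(peaks, genes, window = 1000L, n_bins = 100L)
  v <- unname(pr$matrix[1, ])
  # direct geometry: bins of 20 bp, peak covers [4900,5100) = bins 46..55
  expected <- numeric(100)
  edges <- 4000 + (0:100) * 20
  for (k in 1:100) {
    expected[k] <- max(0, min(5100, edges[k + 1]) - max(4900, edges[k])) / 20
  }
  expect_equal(v, expected)
  expect_equal(v, rev(v))  # symmetric about the centre
  expect_equal(which(v == max(v)), 46:55)
})

test_that("minus-strand profiles are reversed and edge windows marked NA", {
  peaks <- data.frame(contig = "chr1", start = 0L, end = 600L, name = "p")
  genes <- data.frame(gene_id = c("gp", "gm"), contig = "chr1",
                      strand = c("+", "-"), tss = c(500L, 500L))
  pr <- tss_metaprofile(peaks, genes, window = 1000L, n_bins = 10L,
                        contig_lengths = c(chr1 = 100000L))
  # plus strand: window [-500,1500); first 2.5 bins out of range -> NA
  expect_true(all(is.na(pr$matrix["gp", 1:2])))
  expect_equal(unname(pr$matrix["gp", ]), rev(unname(pr$matrix["gm", ])))
})

test_that("promoter assignment uses inclusive 5 kb edge distance", {
  genes <- data.frame(gene_id = "g1", contig = "chr1", strand = "+", tss = 10000L)
  near <- data.frame(contig = "chr1", start = 14000L, end = 14500L, name = "near")
  far <- data.frame(contig = "chr1", start = 15001L, end = 15400L, name = "far")
  spanning <- data.frame(contig = "chr1", start = 9990L, end = 10010L,
                         name = "span")
  exact <- data.frame(contig = "chr1", start = 15000L, end = 15400L,
                      name = "edge5000")
  all_peaks <- rbind(near, far, spanning, exact)
  m <- assign_peaks_to_promoters(all_peaks, genes, max_dist = 5000L)
  expect_setequal(m$g1, c("near", "span", "edge5000"))

  # a peak can serve several genes; a gene can hold several peaks
  genes2 <- rbind(genes, data.frame(gene_id = "g2", contig = "chr1",
                                    strand = "-", tss = 14800L))
  m2 <- assign_peaks_to_promoters(all_peaks, genes2, max_dist = 5000L)
  expect_true("near" %in% m2$g1 && "near" %in% m2$g2)
})

test_that("shrinking the window never adds assignments", {
  sim <- small_genome_with_peaks(seed = 91)
  gm <- generate_gene_models(sim$genome, 25, min_spacing = 1200, seed = 92)
  wide <- assign_peaks_to_promoters(sim$peaks, gm, max_dist = 5000L)
  narrow <- assign_peaks_to_promoters(sim$peaks, gm, max_dist = 1000L)
  expect_true(all(names(narrow) %in% names(wide)))
  for (g in names(narrow)) {
    expect_true(all(narrow[[g]] %in% wide[[g]]))
  }
})

test_that("candidate targets obey the subset chain and count invariants", {
  map <- list(gA = c("p1", "p2"), gB = "p3", gC = "p4")
  flags <- c(p1 = TRUE, p2 = FALSE, p3 = FALSE, p4 = TRUE)
  res <- candidate_direct_targets(c("gA", "gB", "gD"), map, flags)
  expect_equal(res$genes_with_proximal_peak, c("gA", "gB"))
  expect_equal(res$genes_with_motif_peak, "gA")
  expect_equal(res$n_with_proximal_peak, 2L)
  expect_equal(res$n_with_motif_peak, 1L)
  expect_true(all(res$genes_with_motif_peak %in% res$genes_with_proximal_peak))

  # no peaks at all
  none <- candidate_direct_targets(c("gA", "gB"), list(), flags)
  expect_equal(none$n_with_proximal_peak, 0L)
  expect_equal(none$n_with_motif_peak, 0L)

  # saturation: every up gene has a motif-bearing proximal peak
  sat <- candidate_direct_targets(c("gA", "gC"), map[c("gA", "gC")], flags)
  expect_equal(sat$n_with_proximal_peak, 2L)
  expect_equal(sat$n_with_motif_peak, 2L)

  expect_error(candidate_direct_targets("gA", map, flags[1:2]), "no motif flag")
  expect_warning(candidate_direct_targets("gZ", map, flags,
                                          known_genes = c("gA", "gB", "gC")),
                 "absent")
})
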