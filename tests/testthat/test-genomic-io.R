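# FASTA, BED, GTF and PFM readers: coordinate conventions and format errors.

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("FASTA reading handles records, wrapping and case normalisation", {
  g <- read_genome_fasta(write_tmp(c(">chr1", "ACGT"), ".fa"))
  expect_equal(names(g$contigs), "chr1")
  expect_equal(unname(g$lengths), 4L)

  g2 <- read_genome_fasta(write_tmp(c(">chr1", "AC", "GT", ">chr2", "NNNN"), ".fa"))
  expect_equal(unname(g2$lengths), c(4L, 4L))
  expect_equal(unname(g2$contigs[["chr1"]]), "ACGT")

  g3 <- read_genome_fasta(write_tmp(c(">chr1", "acgt"), ".fa"))
  expect_equal(unname(g3$contigs[["chr1"]]), "ACGT")
})

test_that("FASTA format errors are rejected", {
  expect_error(read_genome_fasta(write_tmp(character(), ".fa")))
  expect_error(read_genome_fasta(write_tmp(c(">a", "ACGT", ">a", "GG"), ".fa")),
               "duplicate contig")
  expect_error(read_genome_fasta(write_tmp(c(">a", "ACRT"), ".fa")),
               "outside")
})

test_that("BED parsing follows 0-based half-open convention with defaults", {
  b <- read_bed(write_tmp("chr1\t10\t20", ".bed"))
  expect_equal(b$start, 10L)
  expect_equal(b$end, 20L)
  expect_equal(b$name, "peak_1")
  expect_equal(b$strand, ".")

  b2 <- read_bed(write_tmp("chr1\t10\t20\tp1\t0\t-", ".bed"))
  expect_equal(b2$name, "p1")
  expect_equal(b2$strand, "-")

  expect_error(read_bed(write_tmp("chr1\t20\t10", ".bed")), "line 1")
  expect_error(read_bed(write_tmp("chr1\tten\t20", ".bed")), "non-integer")
})

test_that("BED6 round-trips byte-identically", {
  lines <- c("chr1\t10\t20\tp1\t0\t-",
             "chr2\t0\t5\tp2\t100\t+",
             "chr1\t999\t12345\tp3\t512\t.")
  f <- write_tmp(lines, ".bed")
  out <- tempfile(fileext = ".bed")
  write_bed(read_bed(f), out)
  expect_identical(readLines(out), lines)
})

test_that("GTF TSS extraction converts coordinates and resolves transcripts", {
  gtf <- write_tmp(c(
    'chr1\tx\ttranscript\t101\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr1\tx\ttranscript\t101\t200\t.\t-\t.\tgene_id "gB"; transcript_id "gB.1";',
    'chr1\tx\ttranscript\t151\t250\t.\t+\t.\tgene_id "gC"; transcript_id "gC.1";',
    'chr1\tx\ttranscript\t101\t200\t.\t+\t.\tgene_id "gC"; transcript_id "gC.2";'
  ), ".gtf")
  tss <- read_tss_from_gtf(gtf, canonical_rule = "five_prime_most")
  expect_equal(tss$tss[tss$gene_id == "gA"], 100L)   # 1-based 101 -> 0-based 100
  expect_equal(tss$tss[tss$gene_id == "gB"], 199L)   # minus strand: end - 1
  expect_equal(tss$tss[tss$gene_id == "gC"], 100L)   # five-prime-most of two
  tss2 <- read_tss_from_gtf(gtf, canonical_rule = "first_transcript")
  expect_equal(tss2$tss[tss2$gene_id == "gC"], 150L)
})

test_that("gene models survive a GTF round trip", {
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "chr1",
                      strand = c("+", "-"), tss = c(5000L, 9000L))
  f <- tempfile(fileext = ".gtf")
  write_gene_models_gtf(genes, f)
  back <- read_tss_from_gtf(f)
  expect_equal(back[order(back$gene_id), c("gene_id", "strand", "tss")],
               genes[c("gene_id", "strand", "tss")],
               ignore_attr = TRUE)
})

test_that("PFM parsing accepts plain and bracketed JASPAR dialects", {
  plain <- read_pfm(write_tmp(c(">M1", "4 0", "0 4", "0 0", "0 0"), ".pfm"))
  expect_equal(dim(plain), c(4L, 2L))
  expect_equal(unname(colSums(plain)), c(4, 4))

  brack <- read_pfm(write_tmp(c(">MA0000.1 M1", "A [ 4 0 ]", "C [ 0 4 ]",
                                "G [ 0 0 ]", "T [ 0 0 ]"), ".pfm"))
  expect_equal(unname(brack), unname(plain))

  expect_error(read_pfm(write_tmp(c(">M1", "4 0", "0 4 1", "0 0", "0 0"), ".pfm")),
               "ragged")
  expect_error(read_pfm(write_tmp(c(">M1", "4 -1", "0 4", "0 0", "0 0"), ".pfm")),
               "negative")
})

test_that("PFM files round-trip and support multiple motifs", {
  f <- tempfile(fileext = ".pfm")
  write_pfm(c(list(SOX9 = example_sox9_pcm()), example_decoy_pcms()), f)
  back <- read_pfm(f)
  expect_named(back, c("SOX9", "GLI1", "ZEB1", "CTCF"))
  expect_equal(unname(back$SOX9), unname(example_sox9_pcm()))
})

test_that("differential table reader validates ids and probability columns", {
  f <- write_tmp(c("id\tlog2fc\tpvalue\tfdr", "a\t1\t0.01\t0.02",
                   "b\t-2\t0.5\t0.6"), ".tsv")
  x <- read_differential_tsv(f)
  expect_equal(nrow(x), 2L)
  f2 <- write_tmp(c("id\tlog2fc\tpvalue\tfdr", "a\t1\t0.01\t0.02",
                    "a\t2\t0.1\t0.2"), ".tsv")
  expect_error(read_differential_tsv(f2), "duplicate id")
  f3 <- write_tmp(c("id\tlog2fc\tpvalue\tfdr", "a\t1\t0.01\t1.2"), ".tsv")
  expect_error(read_differential_tsv(f3), "outside")
})
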