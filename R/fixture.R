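# Deterministic promoter-integration fixture: a synthetic genome, peak and
# gene bundle built so the downstream counts are exact by construction —
# 3633 treatment-dependent peaks of which exactly 847 carry a planted
# consensus (23%), 2554 upregulated genes of which exactly 95 have one peak
# within 5 kb of their TSS, and exactly 16 of those genes hold a
# motif-bearing proximal peak. Spontaneous PWM matches inside the 3633 peaks
# are masked by a rescan-and-rewrite loop before planting, so the planted
# counts are the realised counts.

fixture_params <- function() {
  list(n_up_peaks = 3633L, n_motif_peaks = 847L,
       n_up_genes = 2554L, n_down_genes = 3128L, n_null_genes = 500L,
       n_prox_genes = 95L, n_motif_genes = 16L,
       n_down_peaks = 30L, n_null_peaks = 400L,
       gc = 0.41, promoter_window = 5000L)
}

#' Deterministic fixture for the promoter-integration worked example
#'
#' Generates a two-contig genome: one contig holds 95 gene blocks (a TSS with
#' one peak placed 300-4400 bp away) followed by a dense zone of the
#' remaining treatment-dependent, vehicle-dependent and non-significant
#' peaks, all more than 5 kb from any TSS; the second contig holds every
#' other gene and no peaks. The SOX9-like consensus is planted into the
#' proximal peaks of a fixed 16-gene subset and into 831 dense peaks (847
#' total); all other treatment-dependent peaks are scrubbed of spontaneous
#' matches.
#'
#' @param seed Seed (default 42); the bundle is fully deterministic given it.
#' @return List: `genome`, `peaks` (the 3633 treatment-dependent peaks),
#'   `all_peaks`, `peak_table` (differential records for every peak),
#'   `genes` (gene models), `gene_table` (differential gene records), `pcm`,
#'   `pwm` (calibrated), and `truth` — a manifest with the planted positions,
#'   the proximal and motif-bearing gene ids, the gene-to-peak map and the
#'   planted counts.
#' @export
generate_integration_fixture <- function(seed = 42L) {
  p <- fixture_params()
  with_seed(seed, {
    block <- 11000L
    # --- layout: proximal gene blocks on chrP
    i <- seq_len(p$n_prox_genes)
    tss_p <- (i - 1L) * block + 2000L
    dist_i <- 300L + ((i * 37L) %% 42L) * 100L          # 300..4400 bp, edge distance
    width_p <- 350L + (i %% 4L) * 50L
    prox_start <- tss_p + dist_i
    # --- dense peak zone on chrP, > 5 kb from every TSS
    n_dense <- (p$n_up_peaks - p$n_prox_genes) + p$n_down_peaks + p$n_null_peaks
    z0 <- p$n_prox_genes * block + 6000L
    k <- seq_len(n_dense)
    dense_start <- z0 + (k - 1L) * 600L
    dense_width <- 300L + (k %% 5L) * 50L
    chrp_len <- dense_start[n_dense] + dense_width[n_dense] + 1000L
    # --- remaining genes on chrG (no peaks there)
    n_chrg <- (p$n_up_genes - p$n_prox_genes) + p$n_down_genes + p$n_null_genes
    tss_g <- (seq_len(n_chrg) - 1L) * 250L + 100L
    chrg_len <- tss_g[n_chrg] + 400L

    genome <- generate_genome(c(chrp_len, chrg_len), gc = p$gc,
                              seed = sample.int(2147483646L, 1L),
                              contig_names = c("chrP", "chrG"))
    bg <- stats::setNames(c((1 - p$gc) / 2, p$gc / 2, p$gc / 2, (1 - p$gc) / 2),
                          .BASE_CHARS)
    pcm <- example_sox9_pcm()
    pwm <- calibrate_threshold(build_pwm(pcm, background = bg), alpha = 1e-4)
    L <- pwm$length

    n_dense_up <- p$n_up_peaks - p$n_prox_genes
    up_peaks <- data.frame(
      contig = "chrP",
      start = c(prox_start, dense_start[seq_len(n_dense_up)]),
      end = c(prox_start + width_p,
              (dense_start + dense_width)[seq_len(n_dense_up)]),
      name = sprintf("peak_up_%04d", seq_len(p$n_up_peaks)))
    other_idx <- n_dense_up + seq_len(p$n_down_peaks + p$n_null_peaks)
    other_peaks <- data.frame(
      contig = "chrP",
      start = dense_start[other_idx],
      end = (dense_start + dense_width)[other_idx],
      name = c(sprintf("peak_dn_%02d", seq_len(p$n_down_peaks)),
               sprintf("peak_ns_%03d", seq_len(p$n_null_peaks))))

    # --- scrub spontaneous matches from the treatment-dependent peaks
    scan_one <- function(idx, pk) {
      h <- scan_sequence(pwm, get_seq(genome, pk$contig[idx],
                                      pk$start[idx], pk$end[idx]))
      if (nrow(h) == 0L) return(NULL)
      data.frame(row = idx, start = pk$start[idx] + h$start)
    }
    dirty <- seq_len(nrow(up_peaks))
    prob <- c((1 - p$gc) / 2, p$gc / 2, p$gc / 2, (1 - p$gc) / 2)
    for (pass in 1:25) {
      hits <- do.call(rbind, lapply(dirty, scan_one, pk = up_peaks))
      if (is.null(hits)) break
      for (j in seq_len(nrow(hits))) {
        word <- codes_to_seq(sample.int(4L, L, replace = TRUE, prob = prob))
        substr(genome$contigs[["chrP"]], hits$start[j] + 1L,
               hits$start[j] + L) <- word
      }
      dirty <- unique(hits$row)
    }

    # --- plant: 16 proximal peaks + 831 dense treatment-dependent peaks
    motif_gene_idx <- sort(sample(p$n_prox_genes, p$n_motif_genes))
    dense_plant <- p$n_prox_genes +
      sort(sample(n_dense_up, p$n_motif_peaks - p$n_motif_genes))
    plant_rows <- c(motif_gene_idx, dense_plant)
    planted <- data.frame(peak = character(), contig = character(),
                          start = integer(), strand = character())
    for (idx in plant_rows) {
      w <- up_peaks$end[idx] - up_peaks$start[idx]
      off <- up_peaks$start[idx] + sample.int(w - L + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      cons <- consensus_word(pwm)
      word <- if (strand == "+") cons else reverse_complement(cons)
      substr(genome$contigs[["chrP"]], off + 1L, off + L) <- word
      planted <- rbind(planted,
                       data.frame(peak = up_peaks$name[idx], contig = "chrP",
                                  start = off, strand = strand))
    }

    # --- gene models and ids
    prox_ids <- sprintf("gene_up_%04d", seq_len(p$n_prox_genes))
    up_ids <- sprintf("gene_up_%04d", seq_len(p$n_up_genes))
    dn_ids <- sprintf("gene_dn_%04d", seq_len(p$n_down_genes))
    nl_ids <- sprintf("gene_nl_%03d", seq_len(p$n_null_genes))
    chrg_ids <- c(up_ids[-seq_len(p$n_prox_genes)], dn_ids, nl_ids)
    genes <- rbind(
      data.frame(gene_id = prox_ids, contig = "chrP",
                 strand = rep_len(c("+", "-"), p$n_prox_genes), tss = tss_p),
      data.frame(gene_id = chrg_ids, contig = "chrG",
                 strand = rep_len(c("+", "-"), n_chrg), tss = tss_g))

    # --- differential tables
    peak_table <- rbind(
      data.frame(id = up_peaks$name, up_peaks[c("contig", "start", "end")],
                 log2fc = stats::runif(p$n_up_peaks, 1.1, 4),
                 fdr = stats::runif(p$n_up_peaks, 5e-4, 0.049)),
      data.frame(id = other_peaks$name, other_peaks[c("contig", "start", "end")],
                 log2fc = c(stats::runif(p$n_down_peaks, -4, -1.1),
                            stats::runif(p$n_null_peaks, -0.9, 0.9)),
                 fdr = c(stats::runif(p$n_down_peaks, 5e-4, 0.049),
                         stats::runif(p$n_null_peaks, 0.06, 0.95))))
    peak_table$pvalue <- peak_table$fdr * stats::runif(nrow(peak_table), 0.2, 1)
    gene_ids <- c(up_ids, dn_ids, nl_ids)
    gt <- generate_differential_tables(length(gene_ids), p$n_up_genes,
                                       p$n_down_genes, effect_size_lfc = 2,
                                       seed = sample.int(2147483646L, 1L),
                                       gene_ids = gene_ids)

    # internal consistency of the constructed bundle
    flags <- peaks_with_motif(up_peaks, genome, pwm, return_hits = FALSE)$flags
    stopifnot(sum(flags) == p$n_motif_peaks,
              all(flags[up_peaks$name[plant_rows]]))

    truth <- list(
      seed = seed,
      planted = planted,
      n_motif_peaks = p$n_motif_peaks,
      prox_genes = prox_ids,
      motif_genes = prox_ids[motif_gene_idx],
      gene_peak_truth = stats::setNames(as.list(up_peaks$name[seq_len(p$n_prox_genes)]),
                                        prox_ids),
      params = p)

    list(genome = genome, peaks = up_peaks,
         all_peaks = rbind(up_peaks, other_peaks),
         peak_table = peak_table[c("id", "contig", "start", "end",
                                   "log2fc", "pvalue", "fdr")],
         genes = genes, gene_table = gt$table, gene_labels = gt$labels,
         pcm = pcm, pwm = pwm, truth = truth)
  })
}

#' Write a fixture bundle to standard files
#'
#' Emits FASTA (genome), BED (peaks), GTF (gene models), PFM (motif),
#' TSV (differential peak and gene tables) and a JSON truth manifest, so the
#' file-driven pipeline can be run end-to-end on the bundle.
#'
#' @param fixture A bundle from [generate_integration_fixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_fixture_bundle <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    peaks = file.path(dir, "peaks.bed"),
    peak_table = file.path(dir, "peaks_differential.tsv"),
    gtf = file.path(dir, "genes.gtf"),
    gene_table = file.path(dir, "genes_differential.tsv"),
    pfm = file.path(dir, "motif.pfm"),
    truth = file.path(dir, "truth.json"))
  write_genome_fasta(fixture$genome, paths$genome)
  write_bed(fixture$all_peaks, paths$peaks)
  write_differential_tsv(fixture$peak_table, paths$peak_table)
  write_gene_models_gtf(fixture$genes, paths$gtf,
                        contig_lengths = fixture$genome$lengths)
  write_pfm(fixture$pcm, paths$pfm)
  write_differential_tsv(fixture$gene_table, paths$gene_table)
  jsonlite::write_json(fixture$truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
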