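# Synthetic-data generators: genomes, gene models, peak sets, differential
# tables, and motif planting with a ground-truth manifest. Every generator is
# a pure function of (parameters, seed); the caller's RNG state is preserved.

#' Example SOX9-like position count matrix (synthetic)
#'
#' A synthetic 8-bp HMG-box-like count matrix with consensus AACAATGG, built
#' for fixtures and worked examples. It is not any database matrix; real
#' analyses should supply their own PFM via [read_pfm()].
#'
#' @return A 4 x 8 count matrix (rows A, C, G, T) with `name` attribute
#'   `"SOX9"`.
#' @export
example_sox9_pcm <- function() {
  m <- rbind(
    A = c(82,  85,  4, 88, 80,  3,  6,  5),
    C = c( 6,   5, 86,  4,  5,  4,  2,  3),
    G = c( 7,   6,  5,  4,  8,  5, 85, 84),
    T = c( 5,   4,  5,  4,  7, 88,  7,  8)
  )
  attr(m, "name") <- "SOX9"
  m
}

#' Example decoy position count matrices (synthetic)
#'
#' Synthetic count matrices standing in for additional TFs (GLI1-, ZEB1- and
#' CTCF-like shapes) in multi-TF examples; not database matrices.
#'
#' @return Named list of 4 x L count matrices.
#' @export
example_decoy_pcms <- function() {
  gli1 <- rbind(A = c( 4,  4, 82,  3, 82,  4,  4,  5),
                C = c(84,  4,  5, 86,  5,  4, 86,  4),
                G = c( 4,  4,  6,  4,  6,  3,  3, 84),
                T = c( 5, 85,  4,  4,  4, 86,  4,  4))
  zeb1 <- rbind(A = c( 3, 85,  4,  4,  3,  4,  4, 82),
                C = c(86,  4, 86, 86,  4, 84,  5,  5),
                G = c( 4,  4,  3,  3,  4,  5, 84,  5),
                T = c( 4,  4,  4,  4, 86,  4,  4,  5))
  ctcf <- rbind(A = c( 4,  4, 84,  3,  4,  4,  3, 82,  4),
                C = c(85,  86, 5, 87,  4, 86,  4,  5, 86),
                G = c( 4,  3,  4,  3, 85,  4, 86,  6,  4),
                T = c( 4,  4,  4,  4,  4,  3,  4,  4,  3))
  attr(gli1, "name") <- "GLI1"; attr(zeb1, "name") <- "ZEB1"
  attr(ctcf, "name") <- "CTCF"
  list(GLI1 = gli1, ZEB1 = zeb1, CTCF = ctcf)
}

#' Generate a random genome
#'
#' Bases are i.i.d. with `P(G) + P(C) = gc`, split evenly within the GC and
#' AT pairs.
#'
#' @param lengths Integer vector of contig lengths (one contig per entry).
#' @param gc Target GC fraction in (0, 1).
#' @param seed Seed; the generator is deterministic given it.
#' @param contig_names Contig names (default `chr1`, `chr2`, ...).
#' @return A [genome_sequence()] object.
#' @export
generate_genome <- function(lengths, gc = 0.5, seed = 1L,
                            contig_names = sprintf("chr%d", seq_along(lengths))) {
  if (any(lengths <= 0)) stop_fmt("contig lengths must be positive")
  if (gc <= 0 || gc >= 1) stop_fmt("gc must lie in (0, 1)")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(lengths, function(len) {
      codes_to_seq(sample.int(4L, len, replace = TRUE, prob = prob))
    }, character(1))
    names(seqs) <- contig_names
    genome_sequence(seqs)
  })
}

#' Generate gene models with minimum TSS spacing
#'
#' TSS positions are uniform subject to a minimum spacing within each contig
#' (contigs chosen proportionally to length); strands are Bernoulli(0.5).
#'
#' @param genome A [genome_sequence()] object.
#' @param n_genes Number of genes.
#' @param min_spacing Minimum distance between TSSs on a contig, bp.
#' @param seed Seed.
#' @return Data.frame (`gene_id`, `contig`, `strand`, `tss`) sorted by contig
#'   then position.
#' @export
generate_gene_models <- function(genome, n_genes, min_spacing = 2000L, seed = 1L) {
  if (n_genes == 0L) {
    return(data.frame(gene_id = character(), contig = character(),
                      strand = character(), tss = integer()))
  }
  lens <- genome$lengths
  with_seed(seed, {
    contig_of <- sample(names(lens), n_genes, replace = TRUE,
                        prob = as.numeric(lens))
    counts <- table(factor(contig_of, levels = names(lens)))
    rows <- list()
    for (cn in names(lens)) {
      k <- as.integer(counts[[cn]])
      if (k == 0L) next
      slack <- lens[[cn]] - (k - 1L) * min_spacing - 1L
      if (slack < k) {
        stop_fmt("cannot place %d TSSs on %s at spacing %d", k, cn, min_spacing)
      }
      # uniform positions with spacing: sorted draws plus spacing offsets
      base <- sort(sample.int(slack, k))
      tss <- base - 1L + (seq_len(k) - 1L) * min_spacing
      rows[[cn]] <- data.frame(contig = cn, tss = as.integer(tss))
    }
    out <- do.call(rbind, rows)
    out$strand <- sample(c("+", "-"), nrow(out), replace = TRUE)
    out$gene_id <- sprintf("gene_%d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out[c("gene_id", "contig", "strand", "tss")]
  })
}

#' Generate a random peak set
#'
#' Peak lengths follow a normal distribution truncated below at 50 bp;
#' placement is uniform over placeable positions, optionally rejecting
#' overlaps.
#'
#' @param genome A [genome_sequence()] object.
#' @param n_peaks Number of peaks.
#' @param length_mean Mean peak length, bp.
#' @param length_sd SD of peak length, bp.
#' @param seed Seed.
#' @param non_overlapping Reject overlapping placements (bounded retries).
#' @return Data.frame (`contig`, `start`, `end`, `name`), names
#'   `peak_1 ... peak_n`.
#' @export
generate_peaks <- function(genome, n_peaks, length_mean = 400, length_sd = 100,
                           seed = 1L, non_overlapping = FALSE) {
  contig_names <- names(genome$contigs)
  contig_lens <- as.numeric(genome$lengths)
  with_seed(seed, {
    lens <- pmax(50L, as.integer(round(stats::rnorm(n_peaks, length_mean, length_sd))))
    regions <- sample_regions_once(lens, contig_names, contig_lens)
    if (non_overlapping) {
      accepted <- regions[0, ]
      by_c <- list()
      for (i in seq_len(n_peaks)) {
        ok <- FALSE
        for (try in 1:200) {
          r <- if (try == 1L) regions[i, ] else
            sample_regions_once(lens[i], contig_names, contig_lens)
          acc <- by_c[[r$contig]]
          clash <- !is.null(acc) &&
            any(r$start < acc$end & r$end > acc$start)
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok) stop_fmt("could not place non-overlapping peak %d after retries", i)
        by_c[[r$contig]] <- rbind(by_c[[r$contig]], r)
        accepted <- rbind(accepted, r)
      }
      regions <- accepted
    }
    regions$name <- sprintf("peak_%d", seq_len(n_peaks))
    rownames(regions) <- NULL
    regions
  })
}

#' Plant motif consensus words into peaks at a target containment fold
#'
#' First estimates the background containment `p0` (fraction of random,
#' length-matched regions of the unmutated genome holding at least one hit)
#' from `calibration_n` sampled regions; then overwrites a random window in
#' each of a random subset of currently motif-free peaks with the PWM
#' consensus (random strand) until the expected containment reaches
#' `min(1, target_fold * p0)`. Bases outside the named peaks are never
#' altered; coordinates stay valid (overwrite, no insertion).
#'
#' @param genome A [genome_sequence()] object.
#' @param peaks Data.frame of peaks (`contig`, `start`, `end`, `name`).
#' @param pwm A calibrated `pwm`.
#' @param target_fold Target containment fold over background, >= 1.
#' @param seed Seed.
#' @param calibration_n Number of background regions for estimating `p0`.
#' @return List: `genome` (mutated), `truth` — a manifest with `seed`, `p0`,
#'   `target_fold`, `planted` (data.frame `peak`, `contig`, `start`,
#'   `strand`), `n_planted`, `realized_containment`, `realized_fold`.
#' @export
plant_motifs <- function(genome, peaks, pwm, target_fold, seed = 1L,
                         calibration_n = 5000L) {
  if (target_fold < 1) stop_fmt("target_fold must be >= 1")
  if (!is_calibrated(pwm)) stop_fmt("PWM is not calibrated")
  cons <- consensus_word(pwm)
  L <- nchar(cons)
  widths <- peaks$end - peaks$start
  if (L > min(widths)) {
    stop_fmt("consensus length %d exceeds the minimum peak length %d", L, min(widths))
  }
  n <- nrow(peaks)
  with_seed(seed, {
    flags0 <- peaks_with_motif(peaks, genome, pwm, return_hits = FALSE)$flags
    # background containment on the unmutated genome, length-matched regions
    cal_lens <- sample(widths, calibration_n, replace = TRUE)
    cal <- sample_regions_once(cal_lens, names(genome$contigs),
                               as.numeric(genome$lengths))
    hit_idx <- build_hit_index(scan_genome_hits(pwm, genome))
    p0 <- mean(count_hits_in_intervals(cal, hit_idx, L) > 0L)
    planted <- data.frame(peak = character(), contig = character(),
                          start = integer(), strand = character())
    if (target_fold > 1) {
      target_contain <- target_fold * p0
      if (target_contain > 1) stop_fmt("saturated planting: target_fold * p0 = %.3f > 1",
                                       target_contain)
      n_target <- as.integer(round(target_contain * n))
      # top up iteratively: a planted word can flag every peak overlapping
      # its window, so containment is recounted until the target is reached
      flags <- flags0
      for (round_i in 1:25) {
        if (sum(flags) >= n_target) break
        free <- which(!flags)
        if (length(free) == 0L) break
        # plant one word at a time: a word flags every peak overlapping its
        # window, so the deficit is re-evaluated after each placement
        for (i in sample(free)) {
          if (flags[i] || sum(flags) >= n_target) next
          off <- peaks$start[i] + sample.int(widths[i] - L + 1L, 1L) - 1L
          strand <- sample(c("+", "-"), 1L)
          word <- if (strand == "+") cons else reverse_complement(cons)
          cn <- peaks$contig[i]
          substr(genome$contigs[[cn]], off + 1L, off + L) <- word
          planted <- rbind(planted,
                           data.frame(peak = peaks$name[i], contig = cn,
                                      start = off, strand = strand))
          flags[peaks$contig == cn & peaks$start <= off &
                  peaks$end >= off + L] <- TRUE
        }
        # exact recount corrects for hits formed at planted-word flanks
        flags <- peaks_with_motif(peaks, genome, pwm, return_hits = FALSE)$flags
      }
    }
    res <- peaks_with_motif(peaks, genome, pwm, return_hits = FALSE)
    realized <- res$n_with_motif / n
    list(genome = genome,
         truth = list(seed = seed, p0 = p0, target_fold = target_fold,
                      planted = planted, n_planted = nrow(planted),
                      realized_containment = realized,
                      realized_fold = if (p0 > 0) realized / p0 else NA_real_))
  })
}

#' Generate a differential gene table with planted labels
#'
#' Up genes draw `log2fc ~ +|N(effect, 0.5)|` and adjusted p uniform on
#' (0, 0.049); down genes mirror them; null genes draw `log2fc ~ N(0, 0.2)`
#' and adjusted p uniform on (0.05, 1).
#'
#' @param n_genes Total genes.
#' @param n_up,n_down Planted up/down counts (`n_up + n_down <= n_genes`).
#' @param effect_size_lfc Mean |log2 fold change| of planted genes.
#' @param seed Seed.
#' @param gene_ids Optional ids (default `gene_1 ... gene_n`); the first
#'   `n_up` get the up label, the next `n_down` the down label.
#' @return List: `table` (data.frame `id`, `log2fc`, `pvalue`, `fdr`) and
#'   `labels` (named character: up/down/null).
#' @export
generate_differential_tables <- function(n_genes, n_up, n_down,
                                         effect_size_lfc = 2, seed = 1L,
                                         gene_ids = sprintf("gene_%d", seq_len(n_genes))) {
  if (n_up + n_down > n_genes) stop_fmt("n_up + n_down exceeds n_genes")
  with_seed(seed, {
    labels <- rep("null", n_genes)
    labels[seq_len(n_up)] <- "up"
    if (n_down > 0L) labels[n_up + seq_len(n_down)] <- "down"
    lfc <- numeric(n_genes)
    fdr <- numeric(n_genes)
    up <- labels == "up"; down <- labels == "down"; nul <- labels == "null"
    lfc[up] <- abs(stats::rnorm(sum(up), effect_size_lfc, 0.5)) + 1e-6
    fdr[up] <- stats::runif(sum(up), 0, 0.049)
    lfc[down] <- -(abs(stats::rnorm(sum(down), effect_size_lfc, 0.5)) + 1e-6)
    fdr[down] <- stats::runif(sum(down), 0, 0.049)
    lfc[nul] <- stats::rnorm(sum(nul), 0, 0.2)
    fdr[nul] <- stats::runif(sum(nul), 0.05, 1)
    pvalue <- fdr * stats::runif(n_genes, 0.2, 1)
    list(table = data.frame(id = gene_ids, log2fc = lfc,
                            pvalue = pvalue, fdr = fdr),
         labels = stats::setNames(labels, gene_ids))
  })
}
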