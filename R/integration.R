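# TSS-centred accessibility profiles and the promoter-window integration of
# open chromatin with upregulated genes: which up genes hold a differential
# peak within 5 kb of their TSS, and which of those peaks carry a motif.

#' Peak-coverage metaprofile around transcription start sites
#'
#' For each gene, the window `[tss - window, tss + window)` is tiled into
#' `n_bins` bins and each bin's value is the fraction of its bases covered by
#' the union of the peaks. Minus-strand genes have their profile reversed so
#' bins run 5' to 3'. Bins extending past a contig edge are `NA` and excluded
#' from the aggregate (per-bin mean over genes).
#'
#' @param peaks Data.frame of peak intervals (`contig`, `start`, `end`).
#' @param gene_models Data.frame (`gene_id`, `contig`, `strand`, `tss`).
#' @param window Half-width in bp (default 1000).
#' @param n_bins Number of bins tiling the window (default 100).
#' @param contig_lengths Optional named vector (or [genome_sequence()]) used
#'   to flag out-of-range bins.
#' @return List of class `tss_profile`: `matrix` (genes x bins, rownames
#'   gene ids), `column_means`, `window`, `n_bins`.
#' @export
tss_metaprofile <- function(peaks, gene_models, window = 1000L, n_bins = 100L,
                            contig_lengths = NULL) {
  if (inherits(contig_lengths, "genome_sequence")) {
    contig_lengths <- contig_lengths$lengths
  }
  bw <- (2 * window) / n_bins
  merged <- if (nrow(peaks) > 0L) merge_intervals(peaks) else peaks
  by_contig <- if (nrow(peaks) > 0L) split(merged, merged$contig) else list()
  mat <- matrix(0, nrow = nrow(gene_models), ncol = n_bins,
                dimnames = list(gene_models$gene_id, NULL))
  for (i in seq_len(nrow(gene_models))) {
    tss <- gene_models$tss[i]
    w0 <- tss - window
    edges <- w0 + round((0:n_bins) * bw)
    m <- by_contig[[gene_models$contig[i]]]
    vals <- numeric(n_bins)
    if (!is.null(m)) {
      for (k in seq_len(n_bins)) {
        a <- edges[k]; b <- edges[k + 1L]
        ov <- pmin(m$end, b) - pmax(m$start, a)
        vals[k] <- sum(ov[ov > 0]) / (b - a)
      }
    }
    if (!is.null(contig_lengths)) {
      clen <- contig_lengths[[gene_models$contig[i]]]
      out_of_range <- edges[-(n_bins + 1L)] < 0 | edges[-1] > clen
      vals[out_of_range] <- NA_real_
    }
    if (gene_models$strand[i] == "-") vals <- rev(vals)
    mat[i, ] <- vals
  }
  structure(list(matrix = mat,
                 column_means = colMeans(mat, na.rm = TRUE),
                 window = window, n_bins = n_bins),
            class = "tss_profile")
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf("tss_profile: %d gene(s), +/-%d bp in %d bins; mean coverage %.3f\n",
              nrow(x$matrix), x$window, x$n_bins,
              mean(x$column_means, na.rm = TRUE)))
  invisible(x)
}

#' Write a TSS profile matrix and its aggregate as TSV
#'
#' @param profile A `tss_profile`.
#' @param path Output path for the gene x bin matrix; the aggregate goes to
#'   `<path>.aggregate.tsv`.
#' @return Invisibly, `path`.
#' @export
write_tss_profile_tsv <- function(profile, path) {
  m <- data.frame(gene_id = rownames(profile$matrix), profile$matrix,
                  check.names = FALSE)
  names(m)[-1] <- sprintf("bin_%d", seq_len(profile$n_bins))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(bin = seq_len(profile$n_bins), mean_coverage = profile$column_means),
    paste0(path, ".aggregate.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Distance from a TSS point to a peak: 0 when the TSS lies inside
# [start, end); otherwise the distance to the nearer end base.
tss_peak_distance <- function(tss, start, end) {
  ifelse(tss >= start & tss < end, 0L,
         ifelse(tss < start, start - tss, tss - (end - 1L)))
}

#' Assign peaks to gene promoters within a distance window
#'
#' Peak p is assigned to gene g iff the distance from g's TSS to p is at most
#' `max_dist` (inclusive). With `mode = "edge"` (default) distance is 0 when
#' the TSS lies inside the peak and otherwise the distance to the nearer peak
#' edge; `mode = "center"` measures to the peak midpoint. A peak may map to
#' several genes and a gene may hold several peaks.
#'
#' @param peaks Data.frame (`contig`, `start`, `end`, `name`).
#' @param gene_models Data.frame (`gene_id`, `contig`, `strand`, `tss`).
#' @param max_dist Maximum distance in bp (default 5000).
#' @param mode `"edge"` (default) or `"center"`.
#' @return Named list: `gene_id` -> character vector of assigned peak names
#'   (genes with no assigned peak are absent).
#' @export
assign_peaks_to_promoters <- function(peaks, gene_models, max_dist = 5000L,
                                      mode = c("edge", "center")) {
  mode <- match.arg(mode)
  if (nrow(peaks) > 0L && is.null(peaks$name)) {
    peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  }
  out <- list()
  if (nrow(peaks) == 0L || nrow(gene_models) == 0L) return(out)
  by_contig <- split(peaks, peaks$contig)
  by_contig <- lapply(by_contig, function(d) d[order(d$start), , drop = FALSE])
  max_len <- max(peaks$end - peaks$start)
  for (i in seq_len(nrow(gene_models))) {
    d <- by_contig[[gene_models$contig[i]]]
    if (is.null(d)) next
    tss <- gene_models$tss[i]
    # candidate peaks by start position, then exact distance check
    lo <- findInterval(tss - max_dist - max_len, d$start) + 1L
    hi <- findInterval(tss + max_dist, d$start)
    if (hi < lo) next
    sel <- lo:hi
    dist <- if (mode == "edge") {
      tss_peak_distance(tss, d$start[sel], d$end[sel])
    } else {
      abs(tss - floor((d$start[sel] + d$end[sel]) / 2))
    }
    keep <- dist <= max_dist
    if (any(keep)) out[[gene_models$gene_id[i]]] <- d$name[sel][keep]
  }
  out
}

#' Candidate direct target genes: upregulated, promoter-proximal, motif-bearing
#'
#' From the upregulated gene ids and the promoter assignment map, reports the
#' genes with at least one proximal peak and the subset whose proximal peaks
#' include at least one motif-flagged peak. The motif subset is by
#' construction contained in the proximal subset.
#'
#' @param up_gene_ids Character vector of upregulated gene ids.
#' @param gene_peak_map Named list from [assign_peaks_to_promoters()].
#' @param peak_motif_flags Named logical vector covering every peak name in
#'   the map.
#' @param window_bp The distance window used to build the map (recorded).
#' @param known_genes Optional vector of annotated gene ids; up genes outside
#'   it are counted as peak-less with one summary warning.
#' @return List of class `integration_result`: `n_up_genes`,
#'   `genes_with_proximal_peak`, `n_with_proximal_peak`,
#'   `genes_with_motif_peak`, `n_with_motif_peak`, `window_bp`
#'   (gene lists sorted lexicographically).
#' @export
candidate_direct_targets <- function(up_gene_ids, gene_peak_map,
                                     peak_motif_flags, window_bp = 5000L,
                                     known_genes = NULL) {
  all_peaks <- unique(unlist(gene_peak_map, use.names = FALSE))
  missing_flags <- setdiff(all_peaks, names(peak_motif_flags))
  if (length(missing_flags) > 0L) {
    stop_fmt("no motif flag for %d peak(s) in the map (e.g. '%s')",
             length(missing_flags), missing_flags[1])
  }
  if (!is.null(known_genes)) {
    unknown <- setdiff(up_gene_ids, known_genes)
    if (length(unknown) > 0L) {
      warn_fmt("%d upregulated gene(s) absent from the annotation; counted as having no peak",
               length(unknown))
    }
  }
  prox <- intersect(up_gene_ids, names(gene_peak_map))
  motif <- prox[vapply(gene_peak_map[prox],
                       function(pk) any(peak_motif_flags[pk]), logical(1))]
  prox <- sort(prox)
  motif <- sort(motif)
  stopifnot(all(motif %in% prox))
  structure(
    list(n_up_genes = length(up_gene_ids),
         genes_with_proximal_peak = prox,
         n_with_proximal_peak = length(prox),
         genes_with_motif_peak = motif,
         n_with_motif_peak = length(motif),
         window_bp = window_bp),
    class = "integration_result"
  )
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("promoter integration (window %d bp)\n", x$window_bp))
  cat(sprintf("  %d upregulated genes; %d with a proximal peak; %d of those motif-bearing\n",
              x$n_up_genes, x$n_with_proximal_peak, x$n_with_motif_peak))
  invisible(x)
}

#' Write an integration result as JSON and TSV
#'
#' @param x An `integration_result`.
#' @param json_path Output JSON path (counts + gene lists).
#' @param tsv_path Optional TSV path (one row per proximal gene).
#' @return Invisibly, `json_path`.
#' @export
write_integration_result <- function(x, json_path, tsv_path = NULL) {
  jsonlite::write_json(
    list(window_bp = x$window_bp,
         n_up_genes = x$n_up_genes,
         n_with_proximal_peak = x$n_with_proximal_peak,
         n_with_motif_peak = x$n_with_motif_peak,
         genes_with_proximal_peak = x$genes_with_proximal_peak,
         genes_with_motif_peak = x$genes_with_motif_peak),
    json_path, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(tsv_path)) {
    utils::write.table(
      data.frame(gene_id = x$genes_with_proximal_peak,
                 motif_bearing = x$genes_with_proximal_peak %in% x$genes_with_motif_peak),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
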