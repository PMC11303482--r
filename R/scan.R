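# Both-strand PWM scanning. Sequences are scored window-by-window with
# vectorised code-indexing; minus-strand hits are scored against the
# reverse-complemented weight matrix and reported at the forward coordinates
# of the window (peaks are strandless). Windows containing N are skipped.

# Score all windows of `codes` against weight matrix W (4 x L); returns
# 0-based window starts and scores for windows with score >= threshold.
score_windows <- function(codes, W, threshold) {
  L <- ncol(W)
  nw <- length(codes) - L + 1L
  if (nw < 1L) return(list(start = integer(), score = numeric()))
  s <- numeric(nw)
  for (k in seq_len(L)) {
    lut <- c(NA_real_, W[, k])          # code 0 (N) -> NA, skips the window
    s <- s + lut[codes[k:(k + nw - 1L)] + 1L]
  }
  hit <- which(!is.na(s) & s >= threshold)
  list(start = hit - 1L, score = s[hit])
}

# Reverse-complemented weight matrix: complement = reversed row order
# (A<->T, C<->G), positions reversed.
revcomp_weights <- function(W) W[4:1, rev(seq_len(ncol(W))), drop = FALSE]

#' Scan a sequence for PWM hits
#'
#' Every window of the motif length with log2-odds score at or above the
#' calibrated threshold is reported. With `both_strands`, each window's
#' reverse complement is also scored with the same PWM and reported on strand
#' `"-"` at the forward coordinates of the window. Hits are sorted by start,
#' `"+"` before `"-"` at equal start. Windows containing N are skipped.
#'
#' @param pwm A calibrated `pwm` (see [calibrate_threshold()]).
#' @param sequence DNA string over A, C, G, T, N.
#' @param both_strands Scan the reverse complement as well (default TRUE).
#' @return Data.frame of hits: `start` (0-based), `end`, `strand`, `score`.
#' @export
scan_sequence <- function(pwm, sequence, both_strands = TRUE) {
  if (!is_calibrated(pwm)) stop_fmt("PWM is not calibrated; run calibrate_threshold()")
  codes <- seq_to_codes(toupper(sequence))
  L <- pwm$length
  fw <- score_windows(codes, pwm$weights, pwm$threshold)
  hits <- data.frame(start = fw$start, strand = rep("+", length(fw$start)),
                     score = fw$score)
  if (both_strands) {
    rv <- score_windows(codes, revcomp_weights(pwm$weights), pwm$threshold)
    hits <- rbind(hits, data.frame(start = rv$start,
                                   strand = rep("-", length(rv$start)),
                                   score = rv$score))
  }
  hits <- hits[order(hits$start, hits$strand == "-"), , drop = FALSE]
  rownames(hits) <- NULL
  data.frame(start = hits$start, end = hits$start + L,
             strand = hits$strand, score = hits$score)
}

#' Scan whole genome contigs for PWM hits
#'
#' @param pwm A calibrated `pwm`.
#' @param genome A [genome_sequence()] object.
#' @param contigs Contig names to scan (default all).
#' @param both_strands Scan both strands (default TRUE).
#' @return Data.frame of hits: `contig`, `start`, `end`, `strand`, `score`,
#'   sorted by contig then start.
#' @export
scan_genome_hits <- function(pwm, genome, contigs = names(genome$contigs),
                             both_strands = TRUE) {
  parts <- lapply(contigs, function(cn) {
    h <- scan_sequence(pwm, genome$contigs[[cn]], both_strands = both_strands)
    if (nrow(h) == 0L) return(NULL)
    cbind(data.frame(contig = rep(cn, nrow(h))), h)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) {
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric()))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# Count hit windows fully inside each interval given per-contig sorted hit
# starts. `hit_index` is a list: contig -> sorted integer vector of hit starts.
count_hits_in_intervals <- function(intervals, hit_index, L) {
  n <- nrow(intervals)
  cnt <- integer(n)
  for (cn in unique(intervals$contig)) {
    H <- hit_index[[cn]]
    sel <- which(intervals$contig == cn)
    if (is.null(H) || length(H) == 0L) next
    # hit start h lies in a region [s, e) iff s <= h <= e - L
    hi <- findInterval(intervals$end[sel] - L, H)
    lo <- findInterval(intervals$start[sel] - 1L, H)
    cnt[sel] <- hi - lo
  }
  cnt
}

build_hit_index <- function(hits) {
  lapply(split(hits$start, hits$contig), sort)
}

#' Flag peaks containing at least one motif hit
#'
#' A peak is flagged iff scanning its sequence yields one or more hits on
#' either strand; equivalently, iff a genome-wide hit window lies fully
#' inside the peak.
#'
#' @param peaks Data.frame of peaks: `contig`, `start`, `end`, `name`
#'   (0-based half-open).
#' @param genome A [genome_sequence()] object.
#' @param pwm A calibrated `pwm`.
#' @param hits Optional precomputed [scan_genome_hits()] result for reuse.
#' @param return_hits Also return the per-peak hit table (default TRUE).
#' @return List with `flags` (named logical, input order), `n_with_motif`,
#'   and `hits` (data.frame `peak`, `contig`, `start`, `end`, `strand`,
#'   `score`) when `return_hits`.
#' @export
peaks_with_motif <- function(peaks, genome, pwm, hits = NULL, return_hits = TRUE) {
  if (!is_calibrated(pwm)) stop_fmt("PWM is not calibrated; run calibrate_threshold()")
  if (nrow(peaks) == 0L) {
    return(list(flags = stats::setNames(logical(), character()),
                n_with_motif = 0L,
                hits = if (return_hits) data.frame() else NULL))
  }
  if (is.null(peaks$name)) peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  check_intervals_in_genome(peaks, genome, what = "peak")
  if (is.null(hits)) {
    hits <- scan_genome_hits(pwm, genome, contigs = unique(peaks$contig))
  }
  idx <- build_hit_index(hits)
  cnt <- count_hits_in_intervals(peaks, idx, pwm$length)
  flags <- stats::setNames(cnt > 0L, peaks$name)
  out <- list(flags = flags, n_with_motif = sum(flags))
  if (return_hits) {
    per_peak <- vector("list", nrow(peaks))
    with_hits <- which(cnt > 0L)
    for (i in with_hits) {
      h <- hits[hits$contig == peaks$contig[i] &
                  hits$start >= peaks$start[i] &
                  hits$end <= peaks$end[i], , drop = FALSE]
      if (nrow(h) > 0L) {
        per_peak[[i]] <- cbind(data.frame(peak = rep(peaks$name[i], nrow(h))), h)
      }
    }
    per_peak <- per_peak[!vapply(per_peak, is.null, logical(1))]
    out$hits <- if (length(per_peak) > 0L) {
      res <- do.call(rbind, per_peak)
      rownames(res) <- NULL
      res
    } else {
      data.frame(peak = character(), contig = character(), start = integer(),
                 end = integer(), strand = character(), score = numeric())
    }
  }
  out
}

#' Write motif hits as BED6 with a TSV sidecar of raw scores
#'
#' BED scores are scaled to 0-1000 between the PWM's minimum and maximum
#' achievable score, per BED convention; the raw log2-odds scores go to
#' `<path>.scores.tsv`.
#'
#' @param hits Data.frame from [scan_genome_hits()] or [peaks_with_motif()].
#' @param pwm The `pwm` that produced the hits.
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(hits, pwm, path) {
  lo <- pwm_min_score(pwm); hi <- pwm_max_score(pwm)
  scaled <- round(1000 * (hits$score - lo) / max(hi - lo, 1e-12))
  bed <- data.frame(contig = hits$contig, start = hits$start, end = hits$end,
                    name = sprintf("%s_hit_%d", pwm$motif, seq_len(nrow(hits))),
                    score = pmin(1000, pmax(0, scaled)),
                    strand = hits$strand)
  write_bed(bed, path)
  utils::write.table(cbind(bed[c("contig", "start", "end", "name", "strand")],
                           raw_score = hits$score),
                     paste0(path, ".scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
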