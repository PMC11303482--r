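# Permutation motif-enrichment: the observed number of motif-containing
# peaks is compared against random background region sets, length-matched
# one-to-one to the peaks, sampled uniformly from the genome (optionally
# avoiding exclusion intervals or matching GC). Fold enrichment is
# observed / null mean; the empirical p uses the add-one estimator, so it is
# never zero.

# Merge intervals (data.frame contig/start/end) into disjoint sorted pieces.
merge_intervals <- function(x) {
  parts <- lapply(split(x, x$contig), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    s <- d$start; e <- d$end
    keep_s <- s[1]; keep_e <- e[1]
    out_s <- integer(); out_e <- integer()
    if (nrow(d) > 1L) {
      for (i in 2:nrow(d)) {
        if (s[i] <= keep_e) {
          keep_e <- max(keep_e, e[i])
        } else {
          out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
          keep_s <- s[i]; keep_e <- e[i]
        }
      }
    }
    data.frame(contig = d$contig[1], start = c(out_s, keep_s), end = c(out_e, keep_e))
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

# TRUE for each query interval overlapping any merged exclusion interval.
overlaps_excluded <- function(contig, start, end, excl_by_contig) {
  out <- logical(length(start))
  for (cn in unique(contig)) {
    ex <- excl_by_contig[[cn]]
    if (is.null(ex)) next
    sel <- which(contig == cn)
    n_start_lt_end <- findInterval(end[sel] - 1L, ex$start)
    n_end_le_start <- findInterval(start[sel], ex$end)
    out[sel] <- n_start_lt_end > n_end_le_start
  }
  out
}

# GC base count lookup tables: per contig, cumulative count of G/C.
build_gc_cumsum <- function(genome) {
  lapply(genome$contigs, function(s) {
    codes <- seq_to_codes(s)
    cumsum(codes == 2L | codes == 3L)
  })
}

region_gc <- function(contig, start, end, gc_cs) {
  out <- numeric(length(start))
  for (cn in unique(contig)) {
    cs <- gc_cs[[cn]]
    sel <- which(contig == cn)
    lo <- ifelse(start[sel] > 0L, cs[start[sel]], 0)
    out[sel] <- (cs[end[sel]] - lo) / (end[sel] - start[sel])
  }
  out
}

# Draw one set of regions, length-matched to `lengths`, placed uniformly over
# placeable (contig, start) pairs. Uses the current RNG state.
sample_regions_once <- function(lengths, contig_names, contig_lens,
                                excl_by_contig = NULL,
                                gc_match = NULL, gc_targets = NULL, gc_cs = NULL,
                                max_retries = 50L) {
  n <- length(lengths)
  nc <- length(contig_names)
  draw <- function(idx) {
    l <- lengths[idx]
    if (nc == 1L) {
      placeable <- contig_lens[1] - l + 1
      if (any(placeable < 1)) {
        stop_fmt("no placeable position for region length %d", max(l))
      }
      ci <- rep(1L, length(idx))
      st <- floor(stats::runif(length(idx)) * placeable)
    } else {
      ci <- integer(length(idx)); st <- numeric(length(idx))
      for (k in seq_along(idx)) {
        w <- pmax(contig_lens - l[k] + 1, 0)
        if (all(w == 0)) stop_fmt("no placeable position for region length %d", l[k])
        ci[k] <- sample.int(nc, 1L, prob = w)
        st[k] <- floor(stats::runif(1) * w[ci[k]])
      }
    }
    list(ci = ci, st = as.integer(st))
  }
  d <- draw(seq_len(n))
  ci <- d$ci; st <- d$st
  needs_check <- !is.null(excl_by_contig) || !is.null(gc_match)
  if (needs_check) {
    bad <- rep(TRUE, n)
    tries <- 0L
    while (any(bad) && tries < max_retries) {
      cn <- contig_names[ci[bad]]
      s <- st[bad]; e <- s + lengths[bad]
      ok <- rep(TRUE, sum(bad))
      if (!is.null(excl_by_contig)) {
        ok <- ok & !overlaps_excluded(cn, s, e, excl_by_contig)
      }
      if (!is.null(gc_match)) {
        ok <- ok & abs(region_gc(cn, s, e, gc_cs) - gc_targets[bad]) <= gc_match
      }
      idx_bad <- which(bad)
      bad[idx_bad[ok]] <- FALSE
      if (any(bad)) {
        d <- draw(which(bad))
        ci[bad] <- d$ci; st[bad] <- d$st
      }
      tries <- tries + 1L
    }
    if (sum(bad) > 0.1 * n) {
      warn_fmt("background sampling: constraints unmet for %d of %d regions after %d retries",
               sum(bad), n, max_retries)
    }
  }
  data.frame(contig = contig_names[ci], start = st,
             end = st + lengths)
}

#' Sample null background region sets
#'
#' For each of `n_perm` permutations, draws one region per peak length,
#' placed uniformly at random over all placeable positions (contigs weighted
#' by placeable positions). Regions may overlap each other and the peaks
#' unless `exclusions` is given; with `gc_match`, regions are resampled
#' (bounded retries) until their GC is within the tolerance of the matched
#' peak's GC.
#'
#' @param genome A [genome_sequence()] object.
#' @param peak_lengths Integer vector of region lengths to match.
#' @param n_perm Number of permutation sets.
#' @param seed Master seed; each permutation uses a derived child seed.
#' @param exclusions Optional data.frame of intervals to avoid.
#' @param gc_match Optional GC tolerance (e.g. 0.05) for per-region matching.
#' @param gc_targets Target GC per region (required with `gc_match`).
#' @return List of `n_perm` data.frames (`contig`, `start`, `end`).
#' @export
sample_background_regions <- function(genome, peak_lengths, n_perm, seed = 1L,
                                      exclusions = NULL, gc_match = NULL,
                                      gc_targets = NULL) {
  if (n_perm < 1L) stop_fmt("n_perm must be >= 1")
  contig_names <- names(genome$contigs)
  contig_lens <- as.numeric(genome$lengths)
  excl_by_contig <- if (!is.null(exclusions)) {
    m <- merge_intervals(exclusions)
    split(m[c("start", "end")], m$contig)
  }
  gc_cs <- if (!is.null(gc_match)) build_gc_cumsum(genome)
  if (!is.null(gc_match) && is.null(gc_targets)) {
    stop_fmt("gc_match requires gc_targets (one GC value per peak)")
  }
  seeds <- derive_seeds(seed, n_perm)
  lapply(seq_len(n_perm), function(i) {
    with_seed(seeds[i],
              sample_regions_once(peak_lengths, contig_names, contig_lens,
                                  excl_by_contig, gc_match, gc_targets, gc_cs))
  })
}

# Shared core: enrichment of one or more PWMs over the same peaks and the
# same null region geometry.
enrich_core <- function(peaks, genome, pwms, n_perm, seed,
                        exclusions = NULL, gc_match = NULL,
                        statistic = c("containment", "total_hits")) {
  statistic <- match.arg(statistic)
  if (nrow(peaks) == 0L) stop_fmt("peak set is empty")
  if (is.null(peaks$name)) peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  check_intervals_in_genome(peaks, genome, what = "peak")
  for (p in pwms) {
    if (!is_calibrated(p)) stop_fmt("PWM '%s' is not calibrated", p$motif)
  }
  lengths <- peaks$end - peaks$start
  gc_targets <- if (!is.null(gc_match)) {
    region_gc(peaks$contig, peaks$start, peaks$end, build_gc_cumsum(genome))
  }
  idx <- lapply(pwms, function(p) {
    list(index = build_hit_index(scan_genome_hits(p, genome)), L = p$length)
  })
  count_stat <- function(regions, ix) {
    cnt <- count_hits_in_intervals(regions, ix$index, ix$L)
    if (statistic == "containment") sum(cnt > 0L) else sum(cnt)
  }
  observed <- vapply(idx, function(ix) count_stat(peaks, ix), numeric(1))
  null_sets <- sample_background_regions(genome, lengths, n_perm, seed,
                                         exclusions = exclusions,
                                         gc_match = gc_match,
                                         gc_targets = gc_targets)
  null_counts <- vapply(null_sets, function(rg) {
    vapply(idx, function(ix) count_stat(rg, ix), numeric(1))
  }, numeric(length(idx)))
  null_counts <- matrix(null_counts, nrow = length(idx))  # pwms x n_perm
  lapply(seq_along(pwms), function(j) {
    nc <- null_counts[j, ]
    null_mean <- mean(nc)
    null_sd <- stats::sd(nc)
    fold <- if (null_mean > 0) {
      observed[j] / null_mean
    } else {
      warn_fmt("null mean is 0 for motif '%s'; fold reported as Inf", pwms[[j]]$motif)
      Inf
    }
    structure(
      list(tf_name = pwms[[j]]$motif,
           observed_count = observed[j],
           n_peaks = nrow(peaks),
           null_counts = nc,
           null_mean = null_mean,
           null_sd = null_sd,
           fold_enrichment = fold,
           empirical_p = (1 + sum(nc >= observed[j])) / (1 + n_perm),
           z = if (!is.na(null_sd) && null_sd > 0) (observed[j] - null_mean) / null_sd else NA_real_,
           n_perm = n_perm,
           seed = seed,
           statistic = statistic),
      class = "enrichment_result"
    )
  })
}

#' Permutation motif-enrichment test for one motif
#'
#' Compares the number of peaks containing at least one motif hit against the
#' same count over `n_perm` random, length-matched background region sets.
#'
#' @param peaks Data.frame of peaks (`contig`, `start`, `end`, `name`).
#' @param genome A [genome_sequence()] object.
#' @param pwm A calibrated `pwm`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Master seed.
#' @param exclusions Optional interval data.frame the null must avoid.
#' @param gc_match Optional GC tolerance for matched sampling.
#' @param statistic `"containment"` (peaks with >= 1 hit; default) or
#'   `"total_hits"` (total hit-window count).
#' @return An `enrichment_result`: observed count, null summary, fold
#'   enrichment, add-one empirical p, z score.
#' @export
motif_enrichment <- function(peaks, genome, pwm, n_perm = 1000L, seed = 1L,
                             exclusions = NULL, gc_match = NULL,
                             statistic = c("containment", "total_hits")) {
  enrich_core(peaks, genome, list(pwm), n_perm, seed,
              exclusions, gc_match, statistic)[[1]]
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("motif enrichment '%s' (%s statistic)\n", x$tf_name, x$statistic))
  cat(sprintf("  observed %d / %d peaks; null %.2f +/- %.2f over %d permutations\n",
              x$observed_count, x$n_peaks, x$null_mean, x$null_sd, x$n_perm))
  cat(sprintf("  fold %.3f, empirical p %.4g, z %.2f\n",
              x$fold_enrichment, x$empirical_p, x$z))
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(tf = x$tf_name, n_peaks = x$n_peaks, observed = x$observed_count,
             null_mean = x$null_mean, null_sd = x$null_sd,
             fold = x$fold_enrichment, empirical_p = x$empirical_p, z = x$z,
             n_perm = x$n_perm, seed = x$seed)
}

#' Motif enrichment for several TFs over shared null geometry
#'
#' All motifs are tested against the same peaks and the identical null region
#' sets, so folds are directly comparable across TFs.
#'
#' @inheritParams motif_enrichment
#' @param motifs Named list of calibrated `pwm` objects.
#' @return Data.frame, one row per TF (columns as
#'   `as.data.frame.enrichment_result`), sorted by fold descending, ties
#'   broken by motif name; full results in attribute `"results"`.
#' @export
multi_tf_enrichment <- function(peaks, genome, motifs, n_perm = 1000L, seed = 1L,
                                exclusions = NULL, gc_match = NULL,
                                statistic = c("containment", "total_hits")) {
  if (length(motifs) < 1L) stop_fmt("need at least one motif")
  nms <- vapply(motifs, function(p) p$motif, character(1))
  if (anyDuplicated(nms)) {
    stop_fmt("duplicate TF name: %s", nms[duplicated(nms)][1])
  }
  res <- enrich_core(peaks, genome, motifs, n_perm, seed,
                     exclusions, gc_match, statistic)
  tab <- do.call(rbind, lapply(res, as.data.frame))
  ord <- order(-tab$fold, tab$tf)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "results") <- stats::setNames(res, nms)[tab$tf]
  tab
}

#' Count and rounded percentage of motif-containing peaks
#'
#' @param flags Logical vector (one per peak).
#' @return List with `count` and `percent` (rounded to nearest integer).
#' @export
motif_fraction_summary <- function(flags) {
  if (length(flags) == 0L) stop_fmt("empty flag vector")
  count <- sum(flags)
  list(count = as.integer(count),
       percent = as.integer(round(100 * count / length(flags))))
}

#' Write enrichment results as TSV
#'
#' @param x An `enrichment_result`, a list of them, or the data.frame from
#'   [multi_tf_enrichment()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_tsv <- function(x, path) {
  if (inherits(x, "enrichment_result")) x <- list(x)
  tab <- if (is.data.frame(x)) x else do.call(rbind, lapply(x, as.data.frame))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
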