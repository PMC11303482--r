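# Config-driven orchestration: filter -> scan -> enrich -> profile ->
# integrate, with TSV/JSON reports and a run manifest. The config is a plain
# list or a YAML file whose keys mirror the stage-function arguments.

default_config <- function() {
  list(
    paths = list(genome = NULL, peak_table = NULL, gtf = NULL,
                 motifs = NULL, gene_table = NULL),
    thresholds = list(fdr_max = 0.05, fc_min = 1, fc_scale = "log2",
                      alpha = 1e-4, pseudocount = 0.8),
    enrichment = list(n_perm = 1000L, seed = 1L, background = "genome",
                      gc_match = NULL, statistic = "containment"),
    integration = list(window_bp = 5000L, tss_window = 1000L, n_bins = 100L,
                       distance_mode = "edge"),
    out_dir = "results"
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
      merge_config(base[[k]], user[[k]])
    } else {
      user[[k]]
    }
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' @param config A named list, or the path to a YAML file; missing keys take
#'   the documented defaults.
#' @return The validated config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  need <- c("genome", "peak_table", "gtf", "motifs", "gene_table")
  for (k in need) {
    pth <- cfg$paths[[k]]
    if (is.null(pth)) stop_fmt("config: paths$%s is required", k)
    if (!file.exists(pth)) stop_fmt("config: paths$%s not found: %s", k, pth)
  }
  th <- cfg$thresholds
  if (th$fdr_max < 0 || th$fdr_max > 1) stop_fmt("config: fdr_max outside [0,1]")
  if (th$alpha <= 0 || th$alpha > 1) stop_fmt("config: alpha outside (0,1]")
  if (cfg$enrichment$n_perm < 1) stop_fmt("config: n_perm must be >= 1")
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

stage_msg <- function(fmt, ..., t0 = NULL) {
  elapsed <- if (!is.null(t0)) sprintf(" [%.1fs]", as.numeric(Sys.time()) - t0) else ""
  message(sprintf("[peakmotifs] %s%s", sprintf(fmt, ...), elapsed))
}

#' Run the full integration workflow
#'
#' Executes: differential-peak filtering at the stated thresholds; PWM
#' construction and exact threshold calibration for every motif in the PFM
#' file; both-strand scanning of the treatment-dependent peaks; permutation
#' enrichment against random background region sets; the TSS-centred
#' accessibility metaprofile; and the promoter-window integration of
#' upregulated genes with motif-bearing proximal peaks. Writes TSV/JSON
#' reports plus a run manifest (config hash, seed, package version) under
#' `out_dir`.
#'
#' @param config A config list or YAML path (see [read_pipeline_config()]).
#' @return Invisibly, the report list: filtered counts, `enrichment` table,
#'   `motif_fraction`, `integration` result, `tss_profile`, output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  t0 <- as.numeric(Sys.time())
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage_msg("reading inputs")
  genome <- read_genome_fasta(cfg$paths$genome)
  peak_table <- read_differential_tsv(cfg$paths$peak_table)
  gene_table <- read_differential_tsv(cfg$paths$gene_table)
  genes <- read_tss_from_gtf(cfg$paths$gtf)
  pcms <- read_pfm(cfg$paths$motifs)
  if (is.matrix(pcms)) {
    pcms <- stats::setNames(list(pcms), attr(pcms, "name") %||% "motif")
  }

  stage_msg("filtering differential tables", t0 = t0)
  th <- cfg$thresholds
  peak_sets <- filter_differential_peaks(peak_table, fdr_max = th$fdr_max,
                                         fc_min = th$fc_min,
                                         fc_scale = th$fc_scale)
  up_peaks <- peak_sets$up
  up_peaks$name <- up_peaks$id
  gene_sets <- filter_differential_genes(gene_table, adj_p_max = th$fdr_max)

  stage_msg("calibrating %d motif model(s)", length(pcms), t0 = t0)
  bg <- if (identical(cfg$enrichment$background, "genome")) {
    background_from_genome(genome)
  } else {
    uniform_background()
  }
  pwms <- lapply(pcms, function(m) {
    calibrate_threshold(build_pwm(m, background = bg,
                                  pseudocount = th$pseudocount),
                        alpha = th$alpha)
  })

  stage_msg("scanning %d treatment-dependent peaks", nrow(up_peaks), t0 = t0)
  primary <- pwms[[1]]
  scan_res <- peaks_with_motif(up_peaks, genome, primary)
  fraction <- motif_fraction_summary(scan_res$flags)

  stage_msg("permutation enrichment (%d motifs x %d permutations)",
            length(pwms), cfg$enrichment$n_perm, t0 = t0)
  enr <- multi_tf_enrichment(up_peaks, genome, pwms,
                             n_perm = cfg$enrichment$n_perm,
                             seed = cfg$enrichment$seed,
                             gc_match = cfg$enrichment$gc_match,
                             statistic = cfg$enrichment$statistic)

  stage_msg("TSS metaprofile over %d genes", nrow(genes), t0 = t0)
  profile <- tss_metaprofile(up_peaks, genes,
                             window = cfg$integration$tss_window,
                             n_bins = cfg$integration$n_bins,
                             contig_lengths = genome)

  stage_msg("promoter integration (window %d bp)", cfg$integration$window_bp,
            t0 = t0)
  gene_peak_map <- assign_peaks_to_promoters(up_peaks, genes,
                                             max_dist = cfg$integration$window_bp,
                                             mode = cfg$integration$distance_mode)
  integration <- candidate_direct_targets(gene_sets$up, gene_peak_map,
                                          scan_res$flags,
                                          window_bp = cfg$integration$window_bp,
                                          known_genes = genes$gene_id)

  stage_msg("writing reports to %s", cfg$out_dir, t0 = t0)
  out <- function(f) file.path(cfg$out_dir, f)
  write_bed(up_peaks, out("peaks_up.bed"))
  if (nrow(peak_sets$down) > 0L) {
    dn <- peak_sets$down; dn$name <- dn$id
    write_bed(dn, out("peaks_down.bed"))
  }
  write_enrichment_tsv(enr, out("enrichment.tsv"))
  jsonlite::write_json(
    lapply(attr(enr, "results"), function(r) r[setdiff(names(r), "null_counts")]),
    out("enrichment.json"), auto_unbox = TRUE, pretty = TRUE)
  utils::write.table(
    data.frame(tf = rep(enr$tf, each = cfg$enrichment$n_perm),
               null_count = unlist(lapply(attr(enr, "results"),
                                          `[[`, "null_counts"),
                                   use.names = FALSE)),
    out("null_counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_integration_result(integration, out("integration.json"),
                           out("integration.tsv"))
  write_tss_profile_tsv(profile, out("tss_profile.tsv"))

  report <- list(
    n_peaks_up = nrow(peak_sets$up),
    n_peaks_down = nrow(peak_sets$down),
    n_genes_up = length(gene_sets$up),
    n_genes_down = length(gene_sets$down),
    motif_fraction = fraction,
    enrichment = enr,
    integration = integration,
    tss_profile = profile,
    out_dir = cfg$out_dir)

  manifest <- list(
    package_version = as.character(utils::packageVersion("peakmotifs")),
    config = cfg,
    config_hash = config_hash(cfg),
    seed = cfg$enrichment$seed,
    counts = list(peaks_up = report$n_peaks_up, peaks_down = report$n_peaks_down,
                  genes_up = report$n_genes_up, genes_down = report$n_genes_down,
                  motif_peaks = fraction$count, motif_percent = fraction$percent,
                  genes_with_proximal_peak = integration$n_with_proximal_peak,
                  genes_with_motif_peak = integration$n_with_motif_peak))
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_msg("done", t0 = t0)
  invisible(report)
}
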