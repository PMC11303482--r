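#!/usr/bin/env Rscript
# Stage 5: promoter-window integration on the simulated bundle — which
# upregulated genes have a treatment-dependent peak within 5 kb of their
# TSS, and which of those peaks contain a SOX9 motif. On the deterministic
# bundle this reports 95 and 16. Run 01_simulate.R first.

suppressPackageStartupMessages(library(peakmotifs))

scratch <- "scratch/analysis"
genome <- read_genome_fasta(file.path(scratch, "bundle/genome.fa"))
genes <- read_tss_from_gtf(file.path(scratch, "bundle/genes.gtf"))
peak_tab <- read_differential_tsv(file.path(scratch, "bundle/peaks_differential.tsv"))
gene_tab <- read_differential_tsv(file.path(scratch, "bundle/genes_differential.tsv"))
pcm <- read_pfm(file.path(scratch, "bundle/motif.pfm"))

up_peaks <- filter_differential_peaks(peak_tab)$up
up_peaks$name <- up_peaks$id
up_genes <- filter_differential_genes(gene_tab)$up

pwm <- calibrate_threshold(build_pwm(pcm, background = background_from_genome(genome)),
                           alpha = 1e-4)
scan_res <- peaks_with_motif(up_peaks, genome, pwm, return_hits = FALSE)
fr <- motif_fraction_summary(scan_res$flags)
message(sprintf("%d of %d treatment-dependent peaks (%d%%) carry a SOX9 motif",
                fr$count, length(scan_res$flags), fr$percent))

gene_peak_map <- assign_peaks_to_promoters(up_peaks, genes, max_dist = 5000)
res <- candidate_direct_targets(up_genes, gene_peak_map, scan_res$flags,
                                window_bp = 5000, known_genes = genes$gene_id)
print(res)
message(sprintf("candidate direct targets: %s",
                paste(res$genes_with_motif_peak, collapse = ", ")))

write_integration_result(res, "results/integration.json",
                         "results/integration.tsv")
message("wrote results/integration.json, results/integration.tsv")
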