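#!/usr/bin/env Rscript
# Stage 2: apply the stated thresholds to the differential tables of the
# simulated bundle — peaks at FDR <= 0.05 with fold change > 1 (log2 scale),
# genes at adjusted p < 0.05 — and write the selected sets.
# Run 01_simulate.R first.

suppressPackageStartupMessages(library(peakmotifs))

scratch <- "scratch/analysis"
peak_tab <- read_differential_tsv(file.path(scratch, "bundle/peaks_differential.tsv"))
gene_tab <- read_differential_tsv(file.path(scratch, "bundle/genes_differential.tsv"))

peak_sets <- filter_differential_peaks(peak_tab)
gene_sets <- filter_differential_genes(gene_tab)

message(sprintf("treatment-dependent peaks: %d; vehicle-dependent: %d",
                nrow(peak_sets$up), nrow(peak_sets$down)))
message(sprintf("upregulated genes: %d; downregulated: %d",
                length(gene_sets$up), length(gene_sets$down)))

up <- peak_sets$up; up$name <- up$id
write_bed(up, "results/peaks_up.bed")
dn <- peak_sets$down; dn$name <- dn$id
write_bed(dn, "results/peaks_down.bed")
writeLines(gene_sets$up, "results/genes_up.txt")
writeLines(gene_sets$down, "results/genes_down.txt")

write.table(
  data.frame(set = c("peaks_up", "peaks_down", "genes_up", "genes_down"),
             n = c(nrow(peak_sets$up), nrow(peak_sets$down),
                   length(gene_sets$up), length(gene_sets$down))),
  "results/differential_counts.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
message("wrote results/differential_counts.tsv")
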