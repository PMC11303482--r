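---
title: "Motif enrichment and promoter integration for differential ATAC-seq peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif enrichment and promoter integration for differential ATAC-seq peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakmotifs)
```

## The analysis

Endothelial cells exposed to a mesenchymal-transition stimulus (for example
oxidised LDL driving endothelial-to-mesenchymal transition in endothelial
colony-forming cells) remodel both their transcriptome and their open
chromatin. A recurring analysis pattern asks three questions of the paired
ATAC-seq and RNA-seq products:

1. Which regions become more accessible under treatment, at stated
   thresholds (peaks at FDR ≤ 0.05 and fold change > 1; genes at adjusted
   p < 0.05)?
2. Are binding motifs for a candidate transcription factor (here a SOX9-like
   HMG-box motif) over-represented in those treatment-dependent peaks,
   relative to what random genomic regions would contain?
3. Which upregulated genes carry a treatment-dependent, motif-bearing peak
   near their promoter — the candidate direct targets?

`peakmotifs` implements this workflow end-to-end on standard files (FASTA,
BED, GTF, JASPAR-style PFM, TSV differential tables), plus a synthetic-data
module that generates genomes, peaks, gene models and differential tables
with *planted* ground truth, so the whole analysis — and its statistical
calibration — can be exercised at desk scale.

## Motif model and match threshold

A motif arrives as a position count matrix $c_{b,i}$ (rows A, C, G, T). With
background frequencies $q_b$ and a pseudocount $s$ distributed by
background, the match model is the log2-odds position weight matrix

$$ w_{b,i} = \log_2 \frac{f_{b,i}}{q_b}, \qquad
   f_{b,i} = \frac{c_{b,i} + s\,q_b}{N_i + s}, $$

with $N_i$ the column sum. The default pseudocount is $s = 0.8$ (a common
choice that keeps zero counts finite without flattening informative
columns).

A *hit* is a window whose summed weight reaches a calibrated threshold. The
threshold is not a user guess: for a target match p-value $\alpha$ (default
$10^{-4}$, conventional single-site stringency) the exact distribution of
the score of a random L-mer under the background is computed by dynamic
programming on a discretised score grid (step $10^{-3}$ bits), convolving
the per-column score mass functions. The threshold is the smallest
*achievable* score $s$ with $P(\text{score} \ge s) \le \alpha$, lowered by
$L \cdot \text{granularity}/2$ — the exact worst-case per-column rounding
error — so no word whose discretised score clears the cut is lost when true
scores are compared at scan time. The attained tail probability is stored
with the model. The test suite checks this DP against exhaustive
enumeration of all $4^L$ words under uniform and skewed backgrounds.

Scanning is double-stranded: each window is scored as-is and as its reverse
complement (equivalently, with the reverse-complemented matrix), and
minus-strand hits are reported at forward coordinates because peaks are
strandless. Windows containing N are skipped rather than scored against the
background — the conservative choice, since scoring N as background would
let masked sequence accumulate spurious hits.

## Permutation enrichment

The enrichment statistic follows the containment convention: the number of
peaks holding *at least one* hit (a total-hit-count mode is available
behind a flag). The null is built by sampling, for each permutation, one
random region per peak with the same length, uniformly over placeable
positions (contigs weighted by their number of placeable starts). Fold
enrichment is observed divided by the null mean; the empirical p-value uses
the add-one estimator $(1 + \#\{null \ge obs\})/(1 + n_{perm})$, which can
never return 0. With the default 1000 permutations the p-value resolution
is $10^{-3}$. One master seed yields derived per-permutation child seeds,
so results are bit-identical given (inputs, seed), and several motifs can
be tested against the *same* null geometry for directly comparable folds.

Two background-universe options matter in practice:

* **Exclusions.** By default null regions may fall anywhere, including on
  the observed peaks. On a real, multi-gigabase genome the difference is
  negligible. On desk-scale synthetic genomes the peak set can cover a
  large fraction of the sequence, so when motifs have been *planted into
  peaks*, nulls drawn across the peaks re-count the planted signal and
  deflate the fold. The recovery analyses therefore pass
  `exclusions = peaks`, so the null measures background containment outside
  the treatment-dependent regions. Both modes are exposed; the default
  matches the common practice of unconstrained sampling.
* **GC matching.** `gc_match` resamples each null region (bounded retries)
  until its GC is within a tolerance of its matched peak's GC, for analyses
  where composition bias is a concern. It is off by default.

## Planted ground truth

`plant_motifs()` makes enrichment recoverable by construction. It first
estimates the background containment $p_0$ empirically — the fraction of
5000 random length-matched regions of the unmutated genome containing a
hit — rather than from a closed form, so the estimate is robust to the
threshold and background actually in use. The target containment is
$\min(1, \text{fold} \times p_0)$. Words (the PWM consensus, random strand)
are then overwritten into randomly chosen motif-free peaks *one at a time*,
recounting after each placement: on dense synthetic genomes peaks overlap,
so a single planted word can flag several peaks, and batch planting would
overshoot the target. Planting overwrites bases (no insertion), keeping all
coordinates valid, and never touches bases outside the named peaks. A
target fold of exactly 1 plants nothing and returns the genome unchanged.
The returned manifest records $p_0$, every planted position and strand, and
the realised containment, and the tests verify that every planted position
rescans as a hit.

The deterministic integration bundle takes this further: its layout places
95 gene blocks (one TSS, one peak 300–4400 bp away) on one contig, all
remaining peaks in a dense zone more than 5 kb from any TSS, and every
other gene on a second, peak-free contig. Spontaneous PWM matches inside
the treatment-dependent peaks are masked by a rescan-and-rewrite loop
before exactly 847 consensus words are planted (16 of them in the proximal
peaks of a fixed gene subset), so the scan, summary and integration stages
report exact counts — 3633 peaks, 847 (23%) motif-bearing, 95 upregulated
genes with a ≤5 kb peak, 16 of them motif-bearing — every time.

## TSS profiles and promoter integration

`tss_metaprofile()` tiles ±1 kb around each TSS into 100 bins and records
the fraction of each bin covered by the union of the peaks, reversing
minus-strand genes so bins run 5′→3′; bins extending past a contig edge are
marked missing and excluded from the per-bin mean.

"Within 5 kb of the promoter" is operationalised as: distance 0 if the TSS
lies inside the peak, otherwise the distance from the TSS point to the
nearer peak edge, inclusive at exactly 5000 bp. Edge-to-TSS is the
conservative literal reading of a "within 5 kb" rule; a peak-centre mode is
available (`mode = "center"`), and a promoter *span* rather than the TSS
point can be emulated by widening `max_dist`. A peak may serve several
genes and a gene may hold several peaks, since the final counting is per
gene. `candidate_direct_targets()` then intersects: upregulated genes with
at least one assigned peak, and the subset whose assigned peaks include a
motif-bearing one. The subset chain (motif ⊆ proximal ⊆ upregulated) is
asserted on every call.

## Filter semantics

Peak thresholds are read literally from their usual phrasing: FDR
*inclusive* at 0.05, fold change *strict* at 1; gene thresholds use strict
adjusted p < 0.05 with the sign of log2FC deciding direction. Whether
"fold change > 1" means log2 or linear units is genuinely ambiguous in the
literature; the filter defaults to the log2 reading (differential
accessibility tools emit log2 fold changes) and logs the scale in use, with
`fc_scale = "linear"` converting signed log2 values to signed linear folds
first. Significant genes with log2FC exactly 0 are assigned to neither
direction, with a warning.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally (the BED
  convention); GTF is converted on read (TSS of a `+` transcript is
  `start−1`, of a `−` transcript `end−1`) and the canonical TSS per gene
  defaults to the 5′-most transcript, configurable to first-in-file.
* Lowercase (soft-masked) genome sequence is uppercased on read; masking is
  not tracked or used.
* Score-grid granularity $10^{-3}$ bits bounds the threshold error by
  $L \times 10^{-3}$ bits; enrichment conclusions are insensitive at this
  scale.
* Ties in the multi-TF table are broken by motif name for reproducible
  ordering; an all-zero null mean reports fold as `Inf` with a warning
  while the empirical p remains valid.
* Fixed problem sizes used by the shipped analyses and checks, chosen once
  as realistic desk-scale study conditions: recovery datasets use a 2 Mb
  genome at GC 0.41 with 2000 peaks of mean length 400 bp and 1000
  permutations, averaged over 20 replicate seeds; null-calibration runs use
  a 200 kb genome, 500 peaks of mean 300 bp and 199 permutations over 200
  simulated datasets (empirical p on a 1/200 grid).

## What the synthetic data does and does not show

The generators emulate the *downstream products* of a differential
chromatin study — peak intervals with statistics, gene models, differential
gene tables, motif matrices — with i.i.d. background sequence and planted
signal. They do not model read-level noise, fragment-length or
transposase-insertion bias, replicate structure, GC isochores, repeats, or
correlated peak–gene geometry beyond what is planted. Passing the recovery
and calibration tests therefore shows that the *statistics are implemented
correctly and are unbiased under their own assumptions* — not that any
particular biological dataset meets those assumptions. On real data the
choice of motif matrix, match threshold, background universe (whole genome
versus accessible-region or footprint universes) and annotation build all
materially affect absolute folds and gene lists; the package exposes each
of these as an explicit argument rather than fixing a guess.

## Known limitations

* The match model is a zeroth-order (i.i.d.) background; dinucleotide or
  higher-order Markov null models are out of scope.
* De novo motif discovery is out of scope; matrices are user input, and the
  packaged SOX9-like matrix is a synthetic example, not a database matrix.
* The differential statistics themselves (count modelling, dispersion, FDR)
  are consumed, never computed; tables come from upstream tools.
* Peak calling, alignment, and coverage-track generation are out of scope.
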