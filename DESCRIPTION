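Package: peakmotifs
Title: Motif Enrichment and Promoter Integration for Differential ATAC-seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates differential chromatin accessibility with transcription
    factor motif models and expression changes. Filters differential ATAC-seq
    peak and gene tables at stated thresholds, builds log2-odds position weight
    matrices with exact score-distribution threshold calibration, scans peaks on
    both strands, tests motif enrichment against random background region sets
    by permutation, profiles accessibility around transcription start sites,
    and nominates candidate direct target genes whose promoters (within 5 kb)
    hold a motif-bearing treatment-dependent peak. A synthetic-data module
    generates genomes, peaks, gene models and differential tables with planted
    motif enrichment and a ground-truth manifest so the whole workflow runs at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
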