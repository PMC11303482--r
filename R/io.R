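# Readers and writers for the interchange formats the workflow touches:
# BED3/BED6 peaks, JASPAR-style PFM text, differential tables (TSV), and
# TSS extraction from GTF gene models.

#' Read peak intervals from a BED3/BED6 file
#'
#' Coordinates are kept 0-based half-open as in the file. Records missing a
#' name get `peak_<k>` (k = record index); missing strand becomes `"."`.
#' Lines starting with `track`, `browser` or `#` are skipped.
#'
#' @param path Path to a tab-separated BED file.
#' @return A data.frame with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand`, in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_fmt("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_fmt("BED line %d has fewer than 3 fields", lineno[nf < 3L][1])
  }
  contig <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop_fmt("BED line %d: non-integer coordinate", lineno[bad])
  }
  bad <- start >= end | start < 0L
  if (any(bad)) {
    stop_fmt("BED line %d: invalid interval [%d,%d)",
             lineno[bad][1], start[bad][1], end[bad][1])
  }
  name <- ifelse(nf >= 4L,
                 vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "",
                        character(1)),
                 sprintf("peak_%d", seq_len(n)))
  score <- ifelse(nf >= 5L,
                  suppressWarnings(as.numeric(
                    vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "0",
                           character(1)))),
                  0)
  score[is.na(score)] <- 0
  strand <- ifelse(nf >= 6L,
                   vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".",
                          character(1)),
                   ".")
  if (!all(strand %in% c("+", "-", "."))) {
    stop_fmt("BED line %d: invalid strand '%s'",
             lineno[!strand %in% c("+", "-", ".")][1],
             strand[!strand %in% c("+", "-", ".")][1])
  }
  data.frame(contig = contig, start = start, end = end,
             name = name, score = score, strand = strand)
}

#' Write intervals to a BED6 file
#'
#' Inverse of [read_bed()]: BED6 files with integer scores round-trip
#' byte-identically.
#'
#' @param x Data.frame with columns `contig`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  n <- nrow(x)
  name <- x$name %||% sprintf("peak_%d", seq_len(n))
  score <- x$score %||% rep(0, n)
  strand <- x$strand %||% rep(".", n)
  score_chr <- ifelse(score == round(score),
                      format(as.integer(round(score)), trim = TRUE, scientific = FALSE),
                      format(score, trim = TRUE, scientific = FALSE))
  out <- paste(x$contig, x$start, x$end, name, score_chr, strand, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read JASPAR-style position frequency matrices
#'
#' Accepts both whitespace-only rows and bracketed rows (`A [ 4 0 ]`), with
#' or without leading base labels; unlabelled rows are taken in A, C, G, T
#' order. Each motif is a `>`-headed block of four equal-length rows of
#' non-negative counts.
#'
#' @param path Path to a PFM text file (one or more motifs).
#' @return A single 4 x L count matrix (rows A, C, G, T, attribute `name`)
#'   when the file holds one motif, otherwise a named list of such matrices.
#' @export
read_pfm <- function(path) {
  if (!file.exists(path)) stop_fmt("PFM file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_fmt("PFM file %s is empty", path)
  if (!startsWith(lines[1], ">")) {
    stop_fmt("PFM file %s: expected '>' header on first line", path)
  }
  heads <- which(startsWith(lines, ">"))
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    name <- trimws(sub("^>", "", lines[heads[i]]))
    name <- strsplit(name, "\\s+")[[1]]
    name <- name[length(name)]  # JASPAR headers: ">ID NAME"; take the name
    body <- lines[seq(heads[i] + 1L, bounds[i + 1L] - 1L)]
    if (length(body) != 4L) {
      stop_fmt("PFM motif '%s': expected 4 count rows, found %d", name, length(body))
    }
    labels <- toupper(sub("^([A-Za-z]).*$", "\\1", body))
    labelled <- all(labels %in% .BASE_CHARS) && !anyDuplicated(labels)
    rows <- lapply(seq_len(4L), function(j) {
      r <- body[j]
      r <- sub("^[A-Za-z]", "", r)        # drop base label if present
      r <- gsub("[][]", " ", r)           # drop JASPAR brackets
      vals <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
      if (anyNA(vals)) stop_fmt("PFM motif '%s': non-numeric count in row %d", name, j)
      vals
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop_fmt("PFM motif '%s': ragged rows", name)
    }
    m <- do.call(rbind, rows)
    rownames(m) <- if (labelled) labels else .BASE_CHARS
    m <- m[.BASE_CHARS, , drop = FALSE]
    if (any(m < 0)) stop_fmt("PFM motif '%s': negative count", name)
    attr(m, "name") <- name
    out[[name]] <- m
  }
  if (length(out) == 1L) out[[1]] else out
}

#' Write position frequency matrices in JASPAR format
#'
#' @param pcm A 4 x L count matrix, or a named list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pfm <- function(pcm, path) {
  if (is.matrix(pcm)) {
    pcm <- stats::setNames(list(pcm), attr(pcm, "name") %||% "motif")
  }
  out <- character()
  for (nm in names(pcm)) {
    m <- pcm[[nm]]
    out <- c(out, paste0(">", nm),
             vapply(seq_len(4L), function(j) {
               sprintf("%s [ %s ]", .BASE_CHARS[j],
                       paste(format(m[j, ], trim = TRUE), collapse = " "))
             }, character(1)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Extract one TSS per gene from a GTF annotation
#'
#' GTF coordinates are 1-based inclusive; the returned TSS is 0-based.
#' For a `+` transcript the TSS is `start - 1`; for `-` it is `end - 1`.
#' Multiple transcripts per gene are resolved by `canonical_rule`:
#' `"five_prime_most"` (default) takes the most 5' TSS on the gene's strand,
#' `"first_transcript"` takes the first transcript in file order.
#'
#' @param path Path to a GTF file with transcript features.
#' @param canonical_rule `"five_prime_most"` or `"first_transcript"`.
#' @return A data.frame of gene models: `gene_id`, `contig`, `strand`, `tss`
#'   (0-based position), one row per gene.
#' @export
read_tss_from_gtf <- function(path,
                              canonical_rule = c("five_prime_most", "first_transcript")) {
  canonical_rule <- match.arg(canonical_rule)
  g <- rtracklayer::import(path, format = "gtf")
  type <- as.character(g$type)
  tx <- g[type %in% c("transcript", "mRNA")]
  if (length(tx) == 0L) stop_fmt("GTF %s contains no transcript features", path)
  gene_ids_all <- unique(g$gene_id[type == "gene"])
  skipped <- setdiff(gene_ids_all, unique(tx$gene_id))
  if (length(skipped) > 0L) {
    warn_fmt("%d gene(s) with no transcript feature skipped", length(skipped))
  }
  strand <- as.character(BiocGenerics::strand(tx))
  if (any(strand == "*")) stop_fmt("transcript with unknown strand in %s", path)
  df <- data.frame(
    gene_id = tx$gene_id,
    contig = as.character(GenomicRanges::seqnames(tx)),
    strand = strand,
    start1 = BiocGenerics::start(tx),
    end1 = BiocGenerics::end(tx)
  )
  pick <- function(d) {
    if (canonical_rule == "first_transcript") {
      d <- d[1, , drop = FALSE]
    } else if (d$strand[1] == "+") {
      d <- d[which.min(d$start1), , drop = FALSE]
    } else {
      d <- d[which.max(d$end1), , drop = FALSE]
    }
    d
  }
  parts <- split(df, df$gene_id)
  parts <- parts[unique(df$gene_id)]  # keep file order
  res <- do.call(rbind, lapply(parts, pick))
  tss <- ifelse(res$strand == "+", res$start1 - 1L, res$end1 - 1L)
  out <- data.frame(gene_id = res$gene_id, contig = res$contig,
                    strand = res$strand, tss = as.integer(tss))
  rownames(out) <- NULL
  out
}

#' Write gene models as a minimal GTF
#'
#' Each gene gets one `gene` and one `transcript` line whose 5' end sits at
#' the model's TSS; round-tripping through [read_tss_from_gtf()] recovers the
#' same TSS positions.
#'
#' @param genes Data.frame with `gene_id`, `contig`, `strand`, `tss` (0-based).
#' @param path Output path.
#' @param tx_length Transcript span to emit, bp.
#' @param contig_lengths Optional named vector used to clip spans.
#' @return Invisibly, `path`.
#' @export
write_gene_models_gtf <- function(genes, path, tx_length = 1000L,
                                  contig_lengths = NULL) {
  start1 <- ifelse(genes$strand == "+", genes$tss + 1L,
                   pmax(1L, genes$tss + 1L - (tx_length - 1L)))
  end1 <- ifelse(genes$strand == "+", genes$tss + tx_length, genes$tss + 1L)
  if (!is.null(contig_lengths)) {
    end1 <- pmin(end1, contig_lengths[genes$contig])
  }
  fmt <- function(feature) {
    sprintf('%s\tpeakmotifs\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            genes$contig, feature, start1, end1, genes$strand,
            genes$gene_id, paste0(genes$gene_id, ".t1"))
  }
  writeLines(c(rbind(fmt("gene"), fmt("transcript"))), path)
  invisible(path)
}

#' Read a differential table (TSV with header)
#'
#' Expected columns include `id`, `log2fc`, `pvalue`, `fdr`, optionally
#' `contig`, `start`, `end` for peak tables. `pvalue` and `fdr` must lie in
#' \[0, 1\]; no ordering between them is assumed.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data.frame.
#' @export
read_differential_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "log2fc")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop_fmt("differential table %s missing column(s): %s",
             path, paste(miss, collapse = ", "))
  }
  if (anyDuplicated(x$id)) {
    stop_fmt("differential table %s: duplicate id '%s'",
             path, x$id[duplicated(x$id)][1])
  }
  for (col in intersect(c("pvalue", "fdr"), names(x))) {
    if (any(x[[col]] < 0 | x[[col]] > 1, na.rm = TRUE)) {
      stop_fmt("differential table %s: %s outside [0,1]", path, col)
    }
  }
  x
}

#' Write a differential table as TSV
#'
#' @param x Data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_differential_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
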