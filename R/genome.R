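# Genome sequences: a lightweight container over named contig strings.
# All coordinates in this package are 0-based half-open ([start, end)), the
# BED convention; GTF input is converted on read.

#' Construct a genome sequence object
#'
#' A genome is a set of named contigs over the alphabet A, C, G, T, N.
#' Sequences are uppercased; contig names must be unique and non-empty.
#'
#' @param contigs Named character vector of contig sequences.
#' @return An object of class `genome_sequence` with elements `contigs`
#'   (named character) and `lengths` (named integer).
#' @export
genome_sequence <- function(contigs) {
  if (length(contigs) == 0L) stop_fmt("genome has no contigs")
  nm <- names(contigs)
  if (is.null(nm) || any(!nzchar(nm))) stop_fmt("contig names must be non-empty")
  if (anyDuplicated(nm)) {
    stop_fmt("duplicate contig name: %s", nm[duplicated(nm)][1])
  }
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop_fmt("contig %s contains characters outside {A,C,G,T,N}", nm[bad][1])
  }
  structure(
    list(contigs = contigs,
         lengths = stats::setNames(nchar(contigs), nm)),
    class = "genome_sequence"
  )
}

#' Read a genome from a FASTA file
#'
#' Headers are truncated at the first whitespace to form contig names;
#' sequences are uppercased. Lowercase (soft-masked) bases are uppercased and
#' masking is not tracked.
#'
#' @param path Path to a FASTA file.
#' @return A [genome_sequence()] object.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop_fmt("FASTA format error in %s: %s",
                                             path, conditionMessage(e)))
  if (length(x) == 0L) stop_fmt("FASTA file %s contains no records", path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) {
    stop_fmt("duplicate contig name in %s: %s", path, nm[duplicated(nm)][1])
  }
  seqs <- toupper(as.character(x))
  names(seqs) <- nm
  genome_sequence(seqs)
}

#' Write a genome to a FASTA file
#'
#' @param genome A [genome_sequence()] object.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("genome_sequence: %d contig(s), %s bp total\n",
              length(x$contigs), format(sum(x$lengths), big.mark = ",")))
  for (nm in utils::head(names(x$contigs), 10)) {
    cat(sprintf("  %s  %s bp\n", nm, format(x$lengths[[nm]], big.mark = ",")))
  }
  invisible(x)
}

#' Contig lengths of a genome
#'
#' @param genome A [genome_sequence()] object.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) genome$lengths

#' Extract a subsequence (0-based half-open)
#'
#' @param genome A [genome_sequence()] object.
#' @param contig Contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @return Character scalar.
#' @export
get_seq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome$contigs)) stop_fmt("unknown contig: %s", contig)
  len <- genome$lengths[[contig]]
  if (start < 0 || end > len || start >= end) {
    stop_fmt("interval [%d,%d) out of bounds on %s (length %d)",
             start, end, contig, len)
  }
  substr(genome$contigs[[contig]], start + 1L, end)
}

#' GC fraction of a genome (N bases excluded from the denominator)
#'
#' @param genome A [genome_sequence()] object.
#' @return Numeric scalar in \[0, 1\].
#' @export
genome_gc <- function(genome) {
  counts <- integer(5)
  for (s in genome$contigs) {
    codes <- seq_to_codes(s)
    counts <- counts + tabulate(codes + 1L, nbins = 5L)
  }
  acgt <- counts[2:5]
  sum(acgt[c(2, 3)]) / sum(acgt)
}

#' Base frequencies of a genome as a background model
#'
#' @param genome A [genome_sequence()] object.
#' @return Named numeric vector (A, C, G, T) summing to 1; N bases ignored.
#' @export
background_from_genome <- function(genome) {
  counts <- integer(5)
  for (s in genome$contigs) {
    counts <- counts + tabulate(seq_to_codes(s) + 1L, nbins = 5L)
  }
  q <- counts[2:5] / sum(counts[2:5])
  stats::setNames(q, .BASE_CHARS)
}

# Validate that intervals (data.frame contig/start/end) lie inside the genome;
# errors name the offending interval.
check_intervals_in_genome <- function(x, genome, what = "interval") {
  lens <- genome$lengths
  unknown <- !(x$contig %in% names(lens))
  if (any(unknown)) {
    stop_fmt("%s '%s' is on unknown contig '%s'",
             what, x$name[unknown][1] %||% which(unknown)[1], x$contig[unknown][1])
  }
  bad <- x$start < 0 | x$end > lens[x$contig] | x$start >= x$end
  if (any(bad)) {
    stop_fmt("%s '%s' out of contig bounds: %s:[%d,%d)",
             what, x$name[bad][1], x$contig[bad][1], x$start[bad][1], x$end[bad][1])
  }
  invisible(TRUE)
}
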