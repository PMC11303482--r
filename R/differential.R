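# Threshold filters for differential peak and gene tables. The filters do
# not recompute any statistics; they apply the stated cutoffs to consumed
# tables (FDR inclusive at the boundary, fold change strict).

#' Filter a differential peak table into treatment- and vehicle-dependent sets
#'
#' A record passes "up" iff `fdr <= fdr_max` and fold change `> fc_min`;
#' "down" iff `fdr <= fdr_max` and fold change `< -fc_min`. With the default
#' `fc_scale = "log2"` the table's `log2fc` column is compared directly to
#' `fc_min`; with `"linear"` it is first converted to a signed linear fold
#' (`sign(lfc) * 2^|lfc|`). The scale in use is logged because published
#' threshold phrasings are often ambiguous between the two.
#'
#' @param records Data.frame with columns `id`, `log2fc`, `fdr` (and any
#'   interval columns, carried through).
#' @param fdr_max FDR cutoff, inclusive (default 0.05).
#' @param fc_min Fold-change cutoff, strict (default 1).
#' @param fc_scale `"log2"` (default) or `"linear"`.
#' @return List with `up` and `down` (row subsets of `records`) and
#'   `thresholds` (the settings used).
#' @export
filter_differential_peaks <- function(records, fdr_max = 0.05, fc_min = 1,
                                      fc_scale = c("log2", "linear")) {
  fc_scale <- match.arg(fc_scale)
  for (col in c("log2fc", "fdr")) {
    if (is.null(records[[col]])) stop_fmt("differential peak table lacks column '%s'", col)
    if (anyNA(records[[col]])) {
      stop_fmt("record '%s' has missing %s",
               (records$id %||% seq_len(nrow(records)))[is.na(records[[col]])][1], col)
    }
  }
  fc <- if (fc_scale == "log2") {
    records$log2fc
  } else {
    sign(records$log2fc) * 2^abs(records$log2fc)
  }
  sig <- records$fdr <= fdr_max
  up <- records[sig & fc > fc_min, , drop = FALSE]
  down <- records[sig & fc < -fc_min, , drop = FALSE]
  message(sprintf("differential peaks: %d up, %d down (fdr <= %g, |fc| > %g on %s scale)",
                  nrow(up), nrow(down), fdr_max, fc_min, fc_scale))
  list(up = up, down = down,
       thresholds = list(fdr_max = fdr_max, fc_min = fc_min, fc_scale = fc_scale))
}

#' Filter a differential gene table into up- and downregulated id sets
#'
#' A gene is up iff adjusted p `< adj_p_max` and `log2fc > 0`, down iff
#' adjusted p `< adj_p_max` and `log2fc < 0` (strict inequality on p, per the
#' "p < 0.05 after correction" convention). Significant genes with
#' `log2fc == 0` are assigned to neither set, with a warning.
#'
#' @param records Data.frame with columns `id`, `log2fc` and `fdr` (the
#'   adjusted p).
#' @param adj_p_max Adjusted-p cutoff, strict (default 0.05).
#' @return List with `up` and `down` character vectors of gene ids.
#' @export
filter_differential_genes <- function(records, adj_p_max = 0.05) {
  for (col in c("id", "log2fc", "fdr")) {
    if (is.null(records[[col]])) stop_fmt("differential gene table lacks column '%s'", col)
  }
  sig <- records$fdr < adj_p_max
  zero <- sig & records$log2fc == 0
  if (any(zero)) {
    warn_fmt("%d significant gene(s) with log2fc == 0 assigned to neither set",
             sum(zero))
  }
  list(up = records$id[sig & records$log2fc > 0],
       down = records$id[sig & records$log2fc < 0])
}
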