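#' Analysis parameters for the drug-response stack
#'
#' Defaults follow the plate-based drug-screening workflow: principal
#' components 1-4, graph-clustering resolution 1.5, 2000 variable genes,
#' BH-FDR significance at 0.05 with an absolute log2 fold-change cut of
#' 0.25, and the same 0.05 FDR for heatmap gene selection.
#'
#' @param n_pcs number of principal components used downstream.
#' @param cluster_resolution modularity resolution for graph clustering.
#' @param n_variable_genes genes kept by [select_variable_genes()].
#' @param de_alpha FDR threshold for differential expression.
#' @param lfc_cut absolute log2 fold-change threshold.
#' @param heatmap_alpha FDR threshold for heatmap gene selection.
#' @return an `AnalysisParams` list.
#' @export
analysis_params <- function(n_pcs = 4, cluster_resolution = 1.5,
                            n_variable_genes = 2000, de_alpha = 0.05,
                            lfc_cut = 0.25, heatmap_alpha = 0.05) {
  stopifnot(n_pcs >= 1, cluster_resolution > 0, n_variable_genes >= 1,
            de_alpha > 0, de_alpha < 1, lfc_cut > 0,
            heatmap_alpha > 0, heatmap_alpha < 1)
  structure(list(n_pcs = as.integer(n_pcs),
                 cluster_resolution = cluster_resolution,
                 n_variable_genes = as.integer(n_variable_genes),
                 de_alpha = de_alpha, lfc_cut = lfc_cut,
                 heatmap_alpha = heatmap_alpha),
            class = "AnalysisParams")
}

#' log2(CPM + 1) normalization
#'
#' Scales each cell to counts per million and log-transforms:
#' `value(g, c) = log2(1e6 * count(g, c) / total(c) + 1)`.  Inverting the
#' transform recovers per-cell totals of exactly 1e6 CPM.  Cells with zero
#' total counts must be filtered out beforehand; the first offending
#' barcode is named in the error.
#'
#' @param dge a `DGEMatrix` (or plain matrix with dimnames).
#' @return dense genes x cells matrix of log2(CPM + 1) values, with the
#'   source total counts attached as attribute `totals`.
#' @export
cpm_log_normalize <- function(dge) {
  counts <- if (inherits(dge, "DGEMatrix")) dge$counts else dge
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stopf("cell with zero total counts: %s (filter before normalizing)",
          colnames(counts)[which(totals == 0)[1]])
  cpm <- as.matrix(counts) %*% diag(1e6 / totals, length(totals))
  dimnames(cpm) <- dimnames(counts)
  out <- log2(cpm + 1)
  attr(out, "totals") <- totals
  out
}

#' Select highly variable genes by binned dispersion
#'
#' Genes are ranked by dispersion (variance / mean of CPM), standardised
#' within bins of similar mean expression so that the ranking is not a
#' proxy for expression level; the top `n` genes are returned.  Ties break
#' lexicographically for reproducibility.
#'
#' @param norm log2(CPM + 1) matrix from [cpm_log_normalize()].
#' @param n number of genes to return.
#' @param n_bins number of mean-expression bins (default 20).
#' @return character vector of `n` gene ids, most variable first.
#' @export
select_variable_genes <- function(norm, n, n_bins = 20) {
  if (n > nrow(norm)) stopf("n exceeds the number of genes")
  cpm <- 2^norm - 1
  mu <- rowMeans(cpm)
  v <- apply(cpm, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)

  expressed <- mu > 0
  bins <- rep(1L, length(mu))
  if (sum(expressed) > 1) {
    qs <- unique(stats::quantile(mu[expressed], probs = seq(0, 1, length.out = n_bins + 1)))
    bins[expressed] <- as.integer(cut(mu[expressed], breaks = qs,
                                      include.lowest = TRUE))
  }
  z <- disp
  for (b in unique(bins)) {
    sel <- bins == b
    m <- mean(disp[sel]); s <- stats::sd(disp[sel])
    z[sel] <- if (!is.na(s) && s > 0) (disp[sel] - m) / s else 0
  }
  z[disp == 0] <- -Inf  # a gene without variance is never "variable"
  ord <- order(-z, rownames(norm))
  rownames(norm)[ord][seq_len(n)]
}
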