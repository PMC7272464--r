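#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test on two samples.  When both groups have at most
#' `exact_max` observations the p-value is computed by exhaustive
#' enumeration of all group assignments (valid under ties, which keep
#' their midranks); otherwise the normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max exact enumeration when both groups are at most this
#'   size (default 8).
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(x, y, exact_max = 8) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stopf("both groups must be non-empty")
  N <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2

  if (nx <= exact_max && ny <= exact_max) {
    sums <- utils::combn(r, nx, sum)
    dev <- abs(W - mu)
    return(mean(abs(sums - mu) >= dev - 1e-9))
  }

  tab <- table(r)
  tie_term <- sum(tab^3 - tab) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  dev <- W - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon differential expression between two cell groups
#'
#' Per gene, a two-sided rank-sum test of group A against group B on the
#' log2(CPM + 1) values, BH adjustment across the tested family (genes
#' with a nonzero value in at least one cell of either group), and a log2
#' fold change defined as the difference of group means on the
#' log2(CPM + 1) scale.  Direction labels follow the volcano rule:
#' up when `log2fc > lfc_cut` and `fdr < de_alpha`, down when
#' `log2fc < -lfc_cut` and `fdr < de_alpha`, otherwise ns.
#'
#' @param norm log2(CPM + 1) genes x cells matrix.
#' @param cells_a,cells_b barcodes (or column indices) of the two groups;
#'   both must hold at least 2 cells.
#' @param params an `AnalysisParams` (supplies `de_alpha` and `lfc_cut`).
#' @return data.table: `gene_id`, `p_value`, `fdr`, `log2fc`, `direction`.
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, params = analysis_params()) {
  a <- norm[, cells_a, drop = FALSE]
  b <- norm[, cells_b, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    stopf("both groups need at least 2 cells")

  tested <- rowSums(a) + rowSums(b) > 0
  ga <- a[tested, , drop = FALSE]
  gb <- b[tested, , drop = FALSE]
  p <- vapply(seq_len(nrow(ga)),
              function(i) rank_sum_test(ga[i, ], gb[i, ]), numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  log2fc <- rowMeans(ga) - rowMeans(gb)
  direction <- ifelse(fdr < params$de_alpha & log2fc > params$lfc_cut, "up",
                      ifelse(fdr < params$de_alpha & log2fc < -params$lfc_cut,
                             "down", "ns"))
  data.table::data.table(gene_id = rownames(ga), p_value = p, fdr = fdr,
                         log2fc = log2fc, direction = direction)
}

#' Score cell-cycle phases from marker gene sets
#'
#' Each phase score is the mean marker expression minus the mean
#' expression of an expression-matched background set: for every marker,
#' `n_background` genes are sampled (fixed seed) from the same
#' mean-expression quantile bin, markers excluded.  A cell is called S or
#' G2M by the larger of the two scores when that score is positive, and G1
#' otherwise.
#'
#' @param norm log2(CPM + 1) genes x cells matrix.
#' @param s_markers,g2m_markers marker gene ids; markers absent from the
#'   matrix are dropped with a warning, and an error is raised when a
#'   whole list is missing.
#' @param n_background background genes drawn per marker (default 25).
#' @param n_bins expression bins for matching (default 25).
#' @param seed integer RNG seed for background sampling.
#' @return data.table: `barcode`, `s_score`, `g2m_score`,
#'   `phase` in G1/S/G2M.
#' @export
score_cell_cycle <- function(norm, s_markers, g2m_markers,
                             n_background = 25, n_bins = 25, seed = 1) {
  keep_known <- function(markers, label) {
    known <- intersect(markers, rownames(norm))
    if (length(known) == 0)
      stopf("all %s markers missing from the matrix", label)
    if (length(known) < length(markers))
      warning(sprintf("%d %s marker(s) missing from the matrix; dropped",
                      length(markers) - length(known), label))
    known
  }
  s_markers <- keep_known(s_markers, "S")
  g2m_markers <- keep_known(g2m_markers, "G2M")

  mu <- rowMeans(norm)
  qs <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- as.integer(cut(mu, breaks = qs, include.lowest = TRUE))
  names(bins) <- rownames(norm)
  all_markers <- union(s_markers, g2m_markers)

  score_one <- function(markers, salt) {
    bg <- with_seed(stage_seed(seed, salt), {
      unlist(lapply(markers, function(m) {
        pool <- setdiff(names(bins)[bins == bins[[m]]], all_markers)
        if (length(pool) == 0) pool <- setdiff(names(bins), all_markers)
        sample(pool, min(n_background, length(pool)))
      }))
    })
    colMeans(norm[markers, , drop = FALSE]) -
      colMeans(norm[bg, , drop = FALSE])
  }
  s_score <- score_one(s_markers, "cc-s")
  g2m_score <- score_one(g2m_markers, "cc-g2m")

  phase <- ifelse(pmax(s_score, g2m_score) <= 0, "G1",
                  ifelse(s_score >= g2m_score, "S", "G2M"))
  data.table::data.table(barcode = colnames(norm), s_score = s_score,
                         g2m_score = g2m_score, phase = phase)
}

#' Remove additive batch effects with a per-gene linear model
#'
#' Fits, gene by gene, expression on condition plus batch (batch coded
#' sum-to-zero) and subtracts the fitted batch terms, preserving condition
#' means up to the model fit.  Purely additive per-gene batch offsets are
#' removed exactly.  A design in which batch is aliased with condition is
#' rejected.
#'
#' @param norm log2(CPM + 1) genes x cells matrix.
#' @param batch batch label per cell.
#' @param condition optional condition label per cell, protected from
#'   removal.
#' @return adjusted matrix, same shape as `norm`.
#' @export
remove_batch_effect <- function(norm, batch, condition = NULL) {
  batch <- factor(batch)
  if (length(batch) != ncol(norm))
    stopf("batch must have one label per cell")
  if (nlevels(batch) < 2) return(norm)

  Xc <- if (is.null(condition)) {
    matrix(1, ncol(norm), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    condition <- factor(condition)
    if (length(condition) != ncol(norm))
      stopf("condition must have one label per cell")
    stats::model.matrix(~condition)
  }
  Xb <- stats::model.matrix(~batch,
                            contrasts.arg = list(batch = "contr.sum"))[, -1,
                                                                       drop = FALSE]
  X <- cbind(Xc, Xb)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stopf("batch is aliased with condition (design rank %d < %d columns); batch effects cannot be separated",
          qx$rank, ncol(X))
  beta <- qr.coef(qx, t(norm))
  bidx <- seq(ncol(Xc) + 1, ncol(X))
  norm - t(Xb %*% beta[bidx, , drop = FALSE])
}

#' Pseudobulk condition profiles and their correlations
#'
#' Per condition, the mean log2(CPM + 1) over that condition's cells,
#' together with all pairwise Pearson correlations (and their squares)
#' across genes.
#'
#' @param norm log2(CPM + 1) genes x cells matrix.
#' @param conditions condition label per cell; every level must have at
#'   least one cell.
#' @return list with `profiles` (genes x conditions), `r`, `r2`.
#' @export
pseudobulk_profiles <- function(norm, conditions) {
  if (!is.factor(conditions)) conditions <- factor(conditions)
  if (length(conditions) != ncol(norm))
    stopf("conditions must have one label per cell")
  empty <- setdiff(levels(conditions), unique(as.character(conditions)))
  if (length(empty) > 0)
    stopf("condition with zero cells: %s", empty[1])
  profiles <- vapply(levels(conditions), function(cc)
    rowMeans(norm[, conditions == cc, drop = FALSE]), numeric(nrow(norm)))
  r <- stats::cor(profiles)
  list(profiles = profiles, r = r, r2 = r^2)
}

#' Union of significant genes across contrasts for heatmap rendering
#'
#' Collects every gene reaching `fdr < heatmap_alpha` in any contrast and
#' returns the union together with a per-contrast log2 fold-change matrix
#' for rendering (NA where a gene was not tested in a contrast).
#'
#' @param de_list named list of [wilcoxon_de()] result tables, one per
#'   contrast.
#' @param heatmap_alpha FDR cut (default 0.05).
#' @return list with `genes` (sorted union) and `lfc`
#'   (genes x contrasts matrix).
#' @export
heatmap_gene_set <- function(de_list, heatmap_alpha = 0.05) {
  if (length(de_list) == 0) stopf("at least one contrast is required")
  if (is.null(names(de_list)))
    names(de_list) <- paste0("contrast", seq_along(de_list))
  sig <- lapply(de_list, function(de) de$gene_id[de$fdr < heatmap_alpha])
  genes <- sort(Reduce(union, sig))
  lfc <- matrix(NA_real_, length(genes), length(de_list),
                dimnames = list(genes, names(de_list)))
  for (j in seq_along(de_list)) {
    de <- de_list[[j]]
    hit <- match(genes, de$gene_id)
    lfc[, j] <- de$log2fc[hit]
  }
  list(genes = genes, lfc = lfc)
}
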