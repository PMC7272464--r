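#' Principal component analysis of a normalized matrix
#'
#' Genes are centred (not scaled) before the decomposition; columns of the
#' embedding are ordered by decreasing explained variance.  Signs are fixed
#' by convention — each component's largest-magnitude gene loading is made
#' positive — so the embedding is fully deterministic.
#'
#' @param norm log2(CPM + 1) genes x cells matrix.
#' @param n_pcs number of components (needs at least `n_pcs + 1` cells).
#' @return list with `embedding` (cells x n_pcs), `sdev`,
#'   `var_explained` (fraction per kept component), `loadings`.
#' @export
run_pca <- function(norm, n_pcs = 4) {
  n_cells <- ncol(norm)
  if (n_cells < n_pcs + 1)
    stopf("PCA needs at least n_pcs + 1 = %d cells, got %d", n_pcs + 1, n_cells)
  p <- stats::prcomp(t(norm), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(p$x))
  emb <- p$x[, seq_len(k), drop = FALSE]
  load <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      emb[, j] <- -emb[, j]
    }
  }
  list(embedding = emb, sdev = p$sdev,
       var_explained = p$sdev[seq_len(k)]^2 / sum(p$sdev^2),
       loadings = load)
}

#' Cluster cells on a shared-nearest-neighbour graph
#'
#' Builds a k-nearest-neighbour graph in embedding space (Euclidean),
#' weights edges by the Jaccard overlap of the two cells' neighbour sets
#' (each set includes the cell itself), prunes edges below `prune`, and
#' partitions the graph by multi-level modularity optimisation (Louvain)
#' at the given resolution under a fixed seed.  Labels are 0-based,
#' contiguous, ordered by decreasing cluster size.
#'
#' @param embedding cells x dims matrix (e.g. from [run_pca()]).
#' @param resolution modularity resolution (default 1.5).
#' @param k neighbours per cell (default 20, capped at n - 1).
#' @param prune minimum Jaccard weight kept (default 1/15).
#' @param seed integer RNG seed for the community search.
#' @return integer vector of cluster labels, one per cell.
#' @export
cluster_cells <- function(embedding, resolution = 1.5, k = 20,
                          prune = 1 / 15, seed = 1) {
  n <- nrow(embedding)
  if (n < 2) {
    if (n == 1) return(0L)
    stopf("clustering needs at least 1 cell")
  }
  d <- as.matrix(stats::dist(embedding))
  if (all(d == 0)) {
    warning("all cells identical in embedding space; returning one cluster")
    return(rep(0L, n))
  }
  k <- min(k, n - 1)
  # neighbour sets, self included (rank self first via the zero diagonal)
  nb <- apply(d, 1, function(row) order(row)[seq_len(k + 1)])  # (k+1) x n
  memb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) memb[i, nb[, i]] <- TRUE
  shared <- memb %*% t(memb)
  jac <- shared / ((k + 1) * 2 - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0

  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  cl <- with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  labels <- igraph::membership(cl)
  sizes <- sort(table(labels), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  unname(relabel[as.character(labels)])
}
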