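#' Wrap a counts matrix as a DGEMatrix
#'
#' @param counts non-negative genes x cells matrix with gene ids as
#'   rownames and cell barcodes as colnames (dense or sparse).
#' @return a `DGEMatrix`.
#' @export
as_dge <- function(counts) {
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stopf("counts must carry gene ids as rownames and barcodes as colnames")
  if (any(counts < 0)) stopf("counts must be non-negative")
  new_dge(counts)
}

new_dge <- function(counts) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  structure(list(counts = counts,
                 gene_ids = rownames(counts) %||% character(0),
                 cell_barcodes = colnames(counts) %||% character(0)),
            class = "DGEMatrix")
}

#' @export
print.DGEMatrix <- function(x, ...) {
  cat(sprintf("DGEMatrix: %d genes x %d cells, %d molecules\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.DGEMatrix <- function(x) dim(x$counts)

#' Collapse a UMI multiset into a molecule count
#'
#' Distinct UMI sequences are the vertices of a graph with edges joining
#' pairs at Hamming distance <= 1; the molecule count is the number of
#' connected components.  Duplicated sequences fall into one vertex, so PCR
#' duplicates and single-substitution UMI errors both collapse.
#'
#' @param umis character vector (a multiset) of equal-length UMIs.
#' @return integer molecule count.
#' @examples
#' collapse_umis(c("AAAAAAA", "AAAAAAT", "CCCCCCC"))  # 2
#' @export
collapse_umis <- function(umis) {
  if (length(umis) == 0) return(0L)
  cpp_collapse_umis(as.character(umis))
}

#' Build the digital gene expression matrix
#'
#' Groups accepted, gene-assigned tagged reads by (cell barcode, gene) and
#' collapses each group's UMI multiset with [collapse_umis()].  Whitelist
#' cells with no accepted reads appear as all-zero columns; the gene
#' universe and its lexicographic order come from `gene_ids`.
#'
#' @param reads data.frame/data.table with columns `barcode` (whitelisted),
#'   `umi`, `gene_id` (assigned gene).
#' @param whitelist character vector of cell barcodes (column universe, in
#'   whitelist order).
#' @param gene_ids character vector of the gene universe.
#' @return a `DGEMatrix`: list with `counts` (sparse genes x cells integer
#'   matrix), `gene_ids`, `cell_barcodes`.
#' @export
build_dge <- function(reads, whitelist, gene_ids) {
  reads <- data.table::as.data.table(reads)
  gene_ids <- sort(unique(gene_ids))
  if (nrow(reads) > 0) {
    need <- c("barcode", "umi", "gene_id")
    if (!all(need %in% names(reads)))
      stopf("reads need columns barcode, umi, gene_id")
    bad <- !(reads$barcode %in% whitelist)
    if (any(bad))
      stopf("read with non-whitelist barcode reached build_dge: %s",
            reads$barcode[which(bad)[1]])
    if (!all(reads$gene_id %in% gene_ids))
      stopf("read assigned to a gene missing from gene_ids")
  }

  counts <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(length(gene_ids), length(whitelist)),
    dimnames = list(gene_ids, whitelist))
  if (nrow(reads) > 0) {
    gi <- match(reads$gene_id, gene_ids)
    ci <- match(reads$barcode, whitelist)
    grp <- (ci - 1L) * length(gene_ids) + gi
    ord <- order(grp)
    n <- cpp_collapse_by_group(grp[ord], reads$umi[ord])
    grp_u <- unique(grp[ord])
    counts <- Matrix::sparseMatrix(
      i = ((grp_u - 1L) %% length(gene_ids)) + 1L,
      j = ((grp_u - 1L) %/% length(gene_ids)) + 1L,
      x = n,
      dims = c(length(gene_ids), length(whitelist)),
      dimnames = list(gene_ids, whitelist))
  }
  new_dge(counts)
}

#' Write / read a DGE matrix
#'
#' Sparse format is the Matrix Market convention: `matrix.mtx` triplets
#' plus `genes.tsv` and `barcodes.tsv` (one identifier per line) in a
#' directory.  Dense format is a single tab-separated genes-by-cells table
#' whose header row holds the cell barcodes.
#'
#' @param dge a `DGEMatrix`.
#' @param path directory (sparse) or file path (dense).
#' @param format `"mtx"` or `"dense"`.
#' @return `write_dge` returns `path` invisibly; `read_dge` a `DGEMatrix`.
#' @export
write_dge <- function(dge, path, format = c("mtx", "dense")) {
  stopifnot(inherits(dge, "DGEMatrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(dge$counts, file.path(path, "matrix.mtx"))
    writeLines(dge$gene_ids, file.path(path, "genes.tsv"))
    writeLines(dge$cell_barcodes, file.path(path, "barcodes.tsv"))
  } else {
    dense <- as.matrix(dge$counts)
    df <- data.frame(gene_id = dge$gene_ids, dense, check.names = FALSE)
    colnames(df) <- c("gene_id", dge$cell_barcodes)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_dge
#' @export
read_dge <- function(path, format = c("mtx", "dense")) {
  format <- match.arg(format)
  if (format == "mtx") {
    counts <- Matrix::readMM(file.path(path, "matrix.mtx"))
    gene_ids <- readLines(file.path(path, "genes.tsv"))
    barcodes <- readLines(file.path(path, "barcodes.tsv"))
    if (nrow(counts) != length(gene_ids) || ncol(counts) != length(barcodes))
      stopf("matrix dimensions (%d x %d) disagree with identifier files (%d genes, %d barcodes)",
            nrow(counts), ncol(counts), length(gene_ids), length(barcodes))
    dimnames(counts) <- list(gene_ids, barcodes)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "character")
    gene_ids <- df[[1]]
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    counts <- Matrix::Matrix(mat, sparse = TRUE,
                             dimnames = list(gene_ids, colnames(df)[-1]))
  }
  new_dge(counts)
}
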