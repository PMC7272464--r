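#' Build a k-mer index over a transcript reference
#'
#' Every transcript contributes all of its overlapping k-mers to a seed
#' table mapping k-mer to (gene, 1-based position).  The index is the
#' desk-scale stand-in for a genome aligner's reference: reads are later
#' seeded through this table and confirmed by direct comparison against
#' the transcript.
#'
#' @param ref a `ReferenceSet`.
#' @param k seed width in bases; 11 <= k <= Read-2 length (default 21).
#' @return a `GeneIndex`: list with `seeds` (data.table: `kmer`, `gene_id`,
#'   `pos`), `genes` (the reference gene table), `seqs`, and `k`.
#' @examples
#' ref <- generate_reference(2, 60, seed = 1)
#' idx <- build_index(ref, k = 21)
#' nrow(idx$seeds)  # 4 transcripts x (60 - 21 + 1)
#' @export
build_index <- function(ref, k = 21) {
  stopifnot(inherits(ref, "ReferenceSet"))
  if (nrow(ref$genes) == 0) stopf("empty reference")
  if (anyDuplicated(ref$genes$gene_id)) stopf("duplicate gene_id in reference")
  if (!is_count(k, min = 11)) stopf("k must be an integer >= 11")
  if (any(nchar(ref$seqs) < k)) stopf("k exceeds the shortest transcript")

  seeds <- data.table::rbindlist(lapply(seq_along(ref$seqs), function(i) {
    s <- ref$seqs[[i]]
    L <- nchar(s)
    pos <- seq_len(L - k + 1L)
    data.table::data.table(kmer = substring(s, pos, pos + k - 1L),
                           gene_id = names(ref$seqs)[[i]], pos = pos)
  }))
  structure(list(seeds = seeds, genes = ref$genes, seqs = ref$seqs,
                 k = as.integer(k)),
            class = "GeneIndex")
}

#' @export
print.GeneIndex <- function(x, ...) {
  cat(sprintf("GeneIndex: %d genes, k = %d, %d seed entries\n",
              nrow(x$genes), x$k, nrow(x$seeds)))
  invisible(x)
}

#' Assign reads to genes through the k-mer index
#'
#' Candidate genes are gathered from seed hits at three offsets within the
#' read (start, middle, end), in the forward and, optionally, the
#' reverse-complement orientation.  A candidate is confirmed when the full
#' read matches the transcript at the seeded offset with at most
#' `max_mismatches` substitutions.  Exactly one confirmed gene gives an
#' assignment; two or more distinct confirmed genes give `ambiguous`; none
#' gives `unassigned`.
#'
#' @param reads character vector of Read-2 sequences (each >= k bases).
#' @param index a `GeneIndex` from [build_index()].
#' @param max_mismatches substitution tolerance for confirmation
#'   (default 2 for 50-base reads).
#' @param check_rc also check the reverse complement (default TRUE).
#' @return data.table with columns `gene_id` (NA unless assigned) and
#'   `outcome` in assigned/ambiguous/unassigned.
#' @export
assign_reads <- function(reads, index, max_mismatches = 2, check_rc = TRUE) {
  stopifnot(inherits(index, "GeneIndex"))
  if (length(reads) == 0)
    return(data.table::data.table(gene_id = character(0),
                                  outcome = character(0)))
  if (any(nchar(reads) < index$k))
    stopf("read shorter than the seed width k = %d", index$k)
  hit <- cpp_assign_reads(reads, unname(index$seqs), index$k,
                          as.integer(max_mismatches), isTRUE(check_rc))
  gene_id <- rep(NA_character_, length(hit))
  assigned <- hit >= 0
  gene_id[assigned] <- names(index$seqs)[hit[assigned] + 1L]
  outcome <- rep("unassigned", length(hit))
  outcome[assigned] <- "assigned"
  outcome[hit == -2L] <- "ambiguous"
  data.table::data.table(gene_id = gene_id, outcome = outcome)
}

#' @rdname assign_reads
#' @param read2 a single Read-2 sequence.
#' @export
assign_read <- function(read2, index, max_mismatches = 2, check_rc = TRUE) {
  res <- assign_reads(read2, index, max_mismatches, check_rc)
  list(gene_id = res$gene_id[[1]], outcome = res$outcome[[1]])
}
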