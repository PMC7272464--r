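#' Generate a synthetic two-species transcript reference
#'
#' Builds the desk-scale analogue of a concatenated two-species reference:
#' random transcript sequences for two species ("A", analogous to human,
#' gene-id prefix `HUM_`; "B", analogous to mouse, prefix `MUS_`), each gene
#' flagged as mitochondrial or not.  The number of mitochondrial genes per
#' species is `floor(n_genes_per_species * mito_fraction)`, and at least 1
#' when `mito_fraction > 0`.
#'
#' @param n_genes_per_species genes per species (>= 2).
#' @param transcript_length length of every transcript (>= 50, the Read-2
#'   length).
#' @param mito_fraction fraction of genes flagged mitochondrial, in [0, 1).
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @return A `ReferenceSet`: list with `genes` (data.table: `gene_id`,
#'   `species`, `is_mito`) and `seqs` (named character vector of transcript
#'   sequences).
#' @examples
#' ref <- generate_reference(10, 200, mito_fraction = 0.2, seed = 1)
#' table(ref$genes$species, ref$genes$is_mito)
#' @export
generate_reference <- function(n_genes_per_species, transcript_length = 500,
                               mito_fraction = 0, seed = 1) {
  if (!is_count(n_genes_per_species, min = 2))
    stopf("n_genes_per_species must be an integer >= 2, got %s",
          deparse(n_genes_per_species))
  if (!is_count(transcript_length, min = 50))
    stopf("transcript_length must be an integer >= 50 (the Read-2 length)")
  if (!is.numeric(mito_fraction) || mito_fraction < 0 || mito_fraction >= 1)
    stopf("mito_fraction must lie in [0, 1)")

  n <- as.integer(n_genes_per_species)
  n_mito <- as.integer(floor(n * mito_fraction))
  if (mito_fraction > 0) n_mito <- max(1L, n_mito)

  with_seed(seed, {
    make_species <- function(prefix, species) {
      is_mito <- c(rep(TRUE, n_mito), rep(FALSE, n - n_mito))
      id_num <- formatC(seq_len(n), width = 4, flag = "0")
      gene_id <- ifelse(is_mito,
                        paste0(prefix, "MT", id_num),
                        paste0(prefix, "G", id_num))
      data.table::data.table(gene_id = gene_id, species = species,
                             is_mito = is_mito)
    }
    genes <- rbind(make_species("HUM_", "A"), make_species("MUS_", "B"))
    seqs <- random_seq(nrow(genes), transcript_length)
    names(seqs) <- genes$gene_id
    structure(list(genes = genes, seqs = seqs,
                   transcript_length = as.integer(transcript_length)),
              class = "ReferenceSet")
  })
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat(sprintf("ReferenceSet: %d transcripts (%d per species), length %d, %d mitochondrial\n",
              nrow(x$genes), nrow(x$genes) / 2L, x$transcript_length,
              sum(x$genes$is_mito)))
  invisible(x)
}

validate_reference <- function(ref, read2_length = 50) {
  stopifnot(inherits(ref, "ReferenceSet"))
  if (anyDuplicated(ref$genes$gene_id)) stopf("duplicate gene_id in reference")
  pref <- ifelse(ref$genes$species == "A", "HUM_", "MUS_")
  if (!all(startsWith(ref$genes$gene_id, pref)))
    stopf("gene_id prefixes do not match species labels")
  if (any(nchar(ref$seqs) < read2_length))
    stopf("reference transcript shorter than the Read-2 length (%d)", read2_length)
  invisible(TRUE)
}

#' Write / read a reference as FASTA plus a gene table
#'
#' The reference is serialised as a FASTA of transcript sequences and a
#' tab-separated gene table with columns `gene_id`, `species`, `is_mito`.
#'
#' @param ref a `ReferenceSet`.
#' @param fasta path of the FASTA file to write/read.
#' @param gene_table path of the gene-table TSV to write/read.
#' @return `write_reference` returns the paths invisibly; `read_reference`
#'   returns a `ReferenceSet`.
#' @export
write_reference <- function(ref, fasta, gene_table) {
  validate_reference(ref)
  seqs <- Biostrings::DNAStringSet(ref$seqs)
  Biostrings::writeXStringSet(seqs, filepath = fasta)
  utils::write.table(ref$genes, gene_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta, gene_table = gene_table))
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta, gene_table) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  genes <- data.table::fread(gene_table, sep = "\t",
                             colClasses = list(character = c("gene_id", "species"),
                                               logical = "is_mito"))
  if (!setequal(genes$gene_id, names(seqs)))
    stopf("gene table and FASTA disagree on gene ids")
  seq_chr <- as.character(seqs)[genes$gene_id]
  ref <- structure(list(genes = genes, seqs = seq_chr,
                        transcript_length = min(nchar(seq_chr))),
                   class = "ReferenceSet")
  validate_reference(ref)
  ref
}
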