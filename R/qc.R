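#' QC thresholds for plate-based barnyard experiments
#'
#' Bundles the cell-filtering and species-calling thresholds: a per-cell
#' transcript-count window of 5e3 to 6e4 (inclusive), a gene-count window
#' (strictly more than 500 genes, at most `max_genes` — typically 6000 to
#' 10000 depending on the experiment), a mitochondrial-ratio ceiling of
#' 0.05 (strict), a species-calling specificity of 0.9 (strict greater
#' than), and a stricter descriptive specificity of 0.95 used only for
#' reporting.
#'
#' @param transcript_low,transcript_high inclusive transcript-count window.
#' @param min_genes cells must exceed this many detected genes.
#' @param max_genes upper gene-count bound (inclusive).
#' @param max_mito cells must be strictly below this mitochondrial ratio.
#' @param specificity_call species call requires specificity strictly
#'   above this.
#' @param specificity_report descriptive high-purity threshold.
#' @return a `QCThresholds` list.
#' @export
qc_thresholds <- function(transcript_low = 5e3, transcript_high = 6e4,
                          min_genes = 500, max_genes = 6000,
                          max_mito = 0.05, specificity_call = 0.9,
                          specificity_report = 0.95) {
  if (transcript_low >= transcript_high)
    stopf("transcript_low must be below transcript_high")
  if (min_genes >= max_genes) stopf("min_genes must be below max_genes")
  for (v in list(max_mito, specificity_call, specificity_report))
    if (!is.numeric(v) || v <= 0 || v > 1)
      stopf("ratio thresholds must lie in (0, 1]")
  structure(list(transcript_low = transcript_low,
                 transcript_high = transcript_high,
                 min_genes = min_genes, max_genes = max_genes,
                 max_mito = max_mito,
                 specificity_call = specificity_call,
                 specificity_report = specificity_report),
            class = "QCThresholds")
}

#' Per-cell QC statistics for a barnyard DGE
#'
#' For every cell column: total molecules (`n_transcripts`), detected genes
#' (`n_genes`), mitochondrial ratio, per-species specificities (fraction of
#' molecules from species A / B; they sum to 1 whenever the cell has any
#' molecules), the species call, and the well kind from plate metadata
#' (negative wells are identified from the plate design, never inferred
#' from the data; designed doublet wells present themselves as cell wells).
#'
#' @param dge a `DGEMatrix`.
#' @param gene_table data.frame with `gene_id`, `species`, `is_mito`
#'   covering every gene in the DGE.
#' @param plate a `PlateDesign` covering every cell barcode.
#' @param thresholds a `QCThresholds` (for the species call).
#' @return data.table with one row per cell: `barcode`, `well_kind`,
#'   `n_transcripts`, `n_genes`, `mito_ratio`, `specificity_a`,
#'   `specificity_b`, `species_call` (speciesA/speciesB/unidentified).
#'   Cells with zero molecules carry `NA` ratios and an unidentified call.
#' @export
compute_cell_stats <- function(dge, gene_table, plate,
                               thresholds = qc_thresholds()) {
  stopifnot(inherits(dge, "DGEMatrix"))
  gene_table <- data.table::as.data.table(gene_table)
  missing <- setdiff(dge$gene_ids, gene_table$gene_id)
  if (length(missing) > 0)
    stopf("gene(s) missing species/mito annotation: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  ann <- gene_table[match(dge$gene_ids, gene_table$gene_id), ]
  if (anyNA(ann$species) || anyNA(ann$is_mito))
    stopf("gene table has NA species or is_mito annotations")

  counts <- dge$counts
  n_transcripts <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito <- Matrix::colSums(counts[ann$is_mito, , drop = FALSE])
  a <- Matrix::colSums(counts[ann$species == "A", , drop = FALSE])
  b <- Matrix::colSums(counts[ann$species == "B", , drop = FALSE])

  zero <- n_transcripts == 0
  mito_ratio <- ifelse(zero, NA_real_, mito / n_transcripts)
  spec_a <- ifelse(zero, NA_real_, a / n_transcripts)
  spec_b <- ifelse(zero, NA_real_, b / n_transcripts)

  wells <- plate$wells
  kind <- wells$kind[match(dge$cell_barcodes, wells$barcode)]
  if (anyNA(kind)) stopf("DGE contains barcodes absent from the plate design")
  well_kind <- ifelse(kind == "negative", "negative", "cell")

  stats <- data.table::data.table(
    barcode = dge$cell_barcodes,
    well_kind = well_kind,
    n_transcripts = as.numeric(n_transcripts),
    n_genes = as.integer(n_genes),
    mito_ratio = mito_ratio,
    specificity_a = spec_a,
    specificity_b = spec_b)
  stats$species_call <- classify_species(stats, thresholds)
  stats
}

#' Call each cell's species from its specificity
#'
#' A cell is called species A when its species-A specificity strictly
#' exceeds the calling threshold (default 0.9), species B symmetrically,
#' and unidentified otherwise; cells with no molecules are unidentified.
#'
#' @param stats data.frame with `specificity_a`, `specificity_b`,
#'   `n_transcripts` (e.g. from [compute_cell_stats()]).
#' @param thresholds a `QCThresholds`.
#' @return character vector: `"speciesA"`, `"speciesB"`, `"unidentified"`.
#' @export
classify_species <- function(stats, thresholds = qc_thresholds()) {
  cut <- thresholds$specificity_call
  ifelse(is.na(stats$specificity_a) | stats$n_transcripts == 0, "unidentified",
         ifelse(stats$specificity_a > cut, "speciesA",
                ifelse(stats$specificity_b > cut, "speciesB", "unidentified")))
}

#' Transcript-count window filter
#'
#' Keeps cells whose total molecule count lies inside the (inclusive)
#' transcript window, removing both low-capture wells and abnormally high
#' ones.
#'
#' @param stats per-cell statistics from [compute_cell_stats()].
#' @param thresholds a `QCThresholds`.
#' @return logical keep vector aligned with `stats` rows.
#' @export
filter_transcript_window <- function(stats, thresholds = qc_thresholds()) {
  stats$n_transcripts >= thresholds$transcript_low &
    stats$n_transcripts <= thresholds$transcript_high
}

#' Gene-count and mitochondrial-ratio filter
#'
#' Keeps cells whose detected-gene count strictly exceeds `min_genes`, is
#' at most `max_genes`, and whose mitochondrial ratio is strictly below
#' `max_mito`.
#'
#' @inheritParams filter_transcript_window
#' @return logical keep vector aligned with `stats` rows.
#' @export
filter_gene_mito <- function(stats, thresholds = qc_thresholds()) {
  stats$n_genes > thresholds$min_genes &
    stats$n_genes <= thresholds$max_genes &
    !is.na(stats$mito_ratio) & stats$mito_ratio < thresholds$max_mito
}

#' Estimate the ambient-RNA fraction from negative-control wells
#'
#' The estimate is the mean molecule count over negative-control wells
#' divided by the mean over species-identified cell wells — the
#' fraction of a typical cell's molecules that a bead captures from free
#' ambient RNA rather than its own cell.
#'
#' @inheritParams filter_transcript_window
#' @return the ambient fraction (a plain number, e.g. 0.0486 for 4.86%).
#' @export
estimate_ambient <- function(stats) {
  neg <- stats$well_kind == "negative"
  ident <- stats$well_kind == "cell" &
    stats$species_call %in% c("speciesA", "speciesB")
  if (!any(neg)) stopf("ambient estimate unavailable: no negative-control wells")
  if (!any(ident)) stopf("ambient estimate unavailable: no species-identified cells")
  mean(stats$n_transcripts[neg]) / mean(stats$n_transcripts[ident])
}

#' Flag suspected heterogeneous doublets
#'
#' A doublet presents as a species-unidentified profile with an abnormally
#' high molecule count.  Two rules are available and the default flags
#' their union: (fixed) unidentified and above the transcript-window
#' ceiling; (robust) unidentified and above
#' median + 3 * MAD of the identified cells' counts.  With fewer than 3
#' identified cells the robust rule is skipped with a warning.
#' Negative-control wells are never flagged.
#'
#' @inheritParams filter_transcript_window
#' @param rule `"union"` (default), `"fixed"`, or `"robust"`.
#' @return character vector of flagged barcodes.
#' @export
flag_doublets <- function(stats, thresholds = qc_thresholds(),
                          rule = c("union", "fixed", "robust")) {
  rule <- match.arg(rule)
  cells <- stats$well_kind == "cell"
  unident <- cells & stats$species_call == "unidentified"
  fixed <- unident & stats$n_transcripts > thresholds$transcript_high

  ident_counts <- stats$n_transcripts[cells &
    stats$species_call %in% c("speciesA", "speciesB")]
  robust <- rep(FALSE, nrow(stats))
  if (rule != "fixed") {
    if (length(ident_counts) < 3) {
      warning("fewer than 3 identified cells; doublet flagging degrades to the fixed-threshold rule")
      rule <- "fixed"
    } else {
      cutoff <- stats::median(ident_counts) + 3 * stats::mad(ident_counts)
      robust <- unident & stats$n_transcripts > cutoff
    }
  }
  flag <- switch(rule,
                 fixed = fixed,
                 robust = robust,
                 union = fixed | robust)
  stats$barcode[flag]
}

#' Two-species scatter table for barnyard plots
#'
#' Per-cell molecule counts split by species, the table behind the classic
#' barnyard scatter (species-A molecules against species-B molecules).
#'
#' @inheritParams compute_cell_stats
#' @return data.table: `barcode`, `n_species_a`, `n_species_b`,
#'   `well_kind`, `species_call`.
#' @export
barnyard_table <- function(dge, gene_table, plate,
                           thresholds = qc_thresholds()) {
  stats <- compute_cell_stats(dge, gene_table, plate, thresholds)
  data.table::data.table(
    barcode = stats$barcode,
    n_species_a = round(ifelse(is.na(stats$specificity_a), 0,
                               stats$specificity_a * stats$n_transcripts)),
    n_species_b = round(ifelse(is.na(stats$specificity_b), 0,
                               stats$specificity_b * stats$n_transcripts)),
    well_kind = stats$well_kind,
    species_call = stats$species_call)
}
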