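#' Default run configuration
#'
#' All tunable parameters of the pipeline with their standard defaults:
#' the bead read layout (6-bp barcode, 7-bp UMI, 20-bp Read 1, 50-bp
#' Read 2), the QC thresholds (transcript window 5e3-6e4, more than 500
#' and at most 6000 genes, mitochondrial ratio below 0.05, species call
#' above 0.9 specificity), the analysis parameters (4 principal
#' components, clustering resolution 1.5, FDR 0.05, |log2FC| 0.25), and
#' the simulator settings.  Every value can be overridden via `...`.
#'
#' @param ... named overrides of any default.
#' @return a `RunConfig` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    barcode_length = 6, umi_length = 7,
    read1_length = 20, read2_length = 50,
    # simulator
    n_genes_per_species = 200, transcript_length = 500, mito_fraction = 0.05,
    n_cells_a = 96, n_cells_b = 96, n_negative = 32, n_doublets = 0,
    conditions = character(), whitelist_min_distance = 2,
    mean_molecules_per_cell = 5000, ambient_fraction = 0.05,
    dispersion = 0.1, mito_share = 0.02,
    duplication_mean = 3, error_rate = 0.005, window_3prime = 150,
    # counting
    k = 21, max_mismatches = 2,
    # QC
    transcript_low = 5e3, transcript_high = 6e4,
    min_genes = 500, max_genes = 6000, max_mito = 0.05,
    specificity_call = 0.9, specificity_report = 0.95,
    # analysis
    n_pcs = 4, cluster_resolution = 1.5, n_variable_genes = 2000,
    de_alpha = 0.05, lfc_cut = 0.25, heatmap_alpha = 0.05
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0)
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  structure(cfg, class = "RunConfig")
}

config_thresholds <- function(cfg) {
  qc_thresholds(transcript_low = cfg$transcript_low,
                transcript_high = cfg$transcript_high,
                min_genes = cfg$min_genes, max_genes = cfg$max_genes,
                max_mito = cfg$max_mito,
                specificity_call = cfg$specificity_call,
                specificity_report = cfg$specificity_report)
}

config_params <- function(cfg) {
  analysis_params(n_pcs = cfg$n_pcs,
                  cluster_resolution = cfg$cluster_resolution,
                  n_variable_genes = cfg$n_variable_genes,
                  de_alpha = cfg$de_alpha, lfc_cut = cfg$lfc_cut,
                  heatmap_alpha = cfg$heatmap_alpha)
}

#' Read / write a run configuration as YAML
#'
#' @param cfg a `RunConfig`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the yaml package is required for config files")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the yaml package is required for config files")
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' Run the counting pipeline: tagged reads to DGE
#'
#' Chains tag extraction (Read-1 parsing and barcode correction),
#' transcript assignment of Read 2 through the k-mer index, and UMI
#' collapse into the digital gene expression matrix.
#'
#' @param r1_path,r2_path paired FASTQ files.
#' @param plate a `PlateDesign` (supplies the whitelist).
#' @param ref a `ReferenceSet` (supplies the gene universe).
#' @param k seed width for transcript assignment.
#' @param max_mismatches assignment substitution tolerance.
#' @return list with `dge` (a `DGEMatrix`), `tag_stats`, and
#'   `assign_stats` (named counts of assigned/ambiguous/unassigned).
#' @export
count_pipeline <- function(r1_path, r2_path, plate, ref, k = 21,
                           max_mismatches = 2) {
  tagged <- tag_reads(r1_path, r2_path, plate$whitelist)
  index <- build_index(ref, k = k)
  gene_ids <- sort(ref$genes$gene_id)
  if (nrow(tagged$tags) == 0) {
    warning("no accepted read pairs; DGE is empty")
    empty <- data.table::data.table(barcode = character(0),
                                    umi = character(0),
                                    gene_id = character(0))
    dge <- build_dge(empty, plate$whitelist, gene_ids)
    return(list(dge = dge, tag_stats = tagged$stats,
                assign_stats = c(assigned = 0L, ambiguous = 0L, unassigned = 0L)))
  }
  asg <- assign_reads(tagged$tags$read2, index, max_mismatches = max_mismatches)
  assign_stats <- c(assigned = sum(asg$outcome == "assigned"),
                    ambiguous = sum(asg$outcome == "ambiguous"),
                    unassigned = sum(asg$outcome == "unassigned"))
  keep <- asg$outcome == "assigned"
  reads <- data.table::data.table(barcode = tagged$tags$barcode[keep],
                                  umi = tagged$tags$umi[keep],
                                  gene_id = asg$gene_id[keep])
  dge <- build_dge(reads, plate$whitelist, gene_ids)
  list(dge = dge, tag_stats = tagged$stats, assign_stats = assign_stats)
}

ensure_dir <- function(path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  path
}

#' Pipeline stages over an output directory
#'
#' Thin orchestrators binding the package's stages into reproducible,
#' file-based runs; each stage reads its predecessors' outputs from
#' `outdir`, derives its own RNG stream from the global seed, and writes
#' tab-separated results plus the serialised configuration for
#' provenance.  `run_simulate` writes the reference, plate, ground truth
#' and FASTQ pair; `run_count` the DGE (sparse Matrix Market trio);
#' `run_barnyard` the per-cell QC table, barnyard scatter table and
#' ambient estimate; `run_qc` the filter outcomes and the filtered DGE;
#' `run_de` pseudobulk profiles and per-condition DE tables against the
#' first condition label (treated as control); `run_report` a single
#' machine-readable summary of all stage metrics.
#'
#' @param cfg a `RunConfig` from [default_config()].
#' @param outdir run directory.
#' @return each stage returns its main result invisibly.
#' @export
run_simulate <- function(cfg, outdir) {
  ensure_dir(outdir)
  if (requireNamespace("yaml", quietly = TRUE))
    write_config(cfg, file.path(outdir, "config.yaml"))
  ref <- generate_reference(cfg$n_genes_per_species, cfg$transcript_length,
                            cfg$mito_fraction, seed = stage_seed(cfg$seed, "ref"))
  plate <- design_plate(cfg$n_cells_a, cfg$n_cells_b, cfg$n_negative,
                        cfg$n_doublets, cfg$conditions,
                        seed = stage_seed(cfg$seed, "plate"),
                        barcode_length = cfg$barcode_length,
                        min_distance = cfg$whitelist_min_distance)
  truth <- simulate_expression(plate, ref, cfg$mean_molecules_per_cell,
                               cfg$ambient_fraction, de_spec = NULL,
                               dispersion = cfg$dispersion,
                               mito_share = cfg$mito_share,
                               umi_length = cfg$umi_length, seed = cfg$seed)
  write_reference(ref, file.path(outdir, "reference.fasta"),
                  file.path(outdir, "genes_annotation.tsv"))
  write_plate(plate, file.path(outdir, "plate.tsv"))
  utils::write.table(truth$molecules, file.path(outdir, "truth_molecules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rs <- simulate_reads(truth, ref, file.path(outdir, "reads_R1.fastq.gz"),
                       file.path(outdir, "reads_R2.fastq.gz"),
                       duplication_mean = cfg$duplication_mean,
                       error_rate = cfg$error_rate,
                       read2_length = cfg$read2_length,
                       window_3prime = cfg$window_3prime, seed = cfg$seed)
  invisible(list(ref = ref, plate = plate, truth = truth, reads = rs))
}

#' @rdname run_simulate
#' @export
run_count <- function(cfg, outdir) {
  ref <- read_reference(file.path(outdir, "reference.fasta"),
                        file.path(outdir, "genes_annotation.tsv"))
  plate <- read_plate(file.path(outdir, "plate.tsv"))
  res <- count_pipeline(file.path(outdir, "reads_R1.fastq.gz"),
                        file.path(outdir, "reads_R2.fastq.gz"),
                        plate, ref, k = cfg$k,
                        max_mismatches = cfg$max_mismatches)
  write_dge(res$dge, file.path(outdir, "dge"))
  stats <- data.table::data.table(metric = c(names(res$tag_stats),
                                             names(res$assign_stats)),
                                  value = c(res$tag_stats, res$assign_stats))
  utils::write.table(stats, file.path(outdir, "count_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}

#' @rdname run_simulate
#' @export
run_barnyard <- function(cfg, outdir) {
  dge <- read_dge(file.path(outdir, "dge"))
  plate <- read_plate(file.path(outdir, "plate.tsv"))
  genes <- data.table::fread(file.path(outdir, "genes_annotation.tsv"))
  thr <- config_thresholds(cfg)
  stats <- compute_cell_stats(dge, genes, plate, thr)
  scatter <- barnyard_table(dge, genes, plate, thr)
  amb <- tryCatch(estimate_ambient(stats), error = function(e) NA_real_)
  utils::write.table(stats, file.path(outdir, "cell_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scatter, file.path(outdir, "barnyard_scatter.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("ambient_fraction\t%.6f", amb),
             file.path(outdir, "ambient_estimate.tsv"))
  invisible(list(stats = stats, ambient = amb))
}

#' @rdname run_simulate
#' @export
run_qc <- function(cfg, outdir) {
  dge <- read_dge(file.path(outdir, "dge"))
  stats <- data.table::fread(file.path(outdir, "cell_stats.tsv"))
  thr <- config_thresholds(cfg)
  keep_window <- filter_transcript_window(stats, thr)
  keep_gene <- filter_gene_mito(stats, thr)
  doublets <- flag_doublets(stats, thr)
  keep <- keep_window & keep_gene & stats$well_kind == "cell" &
    !(stats$barcode %in% doublets)
  out <- data.table::data.table(stats,
                                pass_transcript_window = keep_window,
                                pass_gene_mito = keep_gene,
                                doublet_flag = stats$barcode %in% doublets,
                                keep = keep)
  utils::write.table(out, file.path(outdir, "qc_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  filtered <- new_dge(dge$counts[, keep, drop = FALSE])
  write_dge(filtered, file.path(outdir, "dge_filtered"))
  invisible(list(qc = out, dge = filtered))
}

#' @rdname run_simulate
#' @export
run_de <- function(cfg, outdir) {
  dge <- read_dge(file.path(outdir, "dge_filtered"))
  plate <- read_plate(file.path(outdir, "plate.tsv"))
  params <- config_params(cfg)
  norm <- cpm_log_normalize(dge)
  cond <- plate$wells$condition[match(dge$cell_barcodes, plate$wells$barcode)]
  if (all(is.na(cond)))
    stopf("no condition labels on this plate; nothing to contrast")
  control <- cfg$conditions[1] %||% sort(unique(cond))[1]
  de_list <- list()
  for (cc in setdiff(unique(cond[!is.na(cond)]), control)) {
    de <- wilcoxon_de(norm, dge$cell_barcodes[which(cond == cc)],
                      dge$cell_barcodes[which(cond == control)], params)
    de_list[[cc]] <- de
    utils::write.table(de, file.path(outdir, sprintf("de_%s_vs_%s.tsv", cc, control)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pb <- pseudobulk_profiles(norm, cond)
  utils::write.table(data.frame(gene_id = rownames(pb$profiles), pb$profiles),
                     file.path(outdir, "pseudobulk.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(de = de_list, pseudobulk = pb))
}

#' @rdname run_simulate
#' @export
run_report <- function(cfg, outdir) {
  files <- c("count_stats.tsv", "ambient_estimate.tsv", "qc_table.tsv")
  lines <- c(sprintf("run report: %s", normalizePath(outdir)))
  cs_path <- file.path(outdir, "count_stats.tsv")
  if (file.exists(cs_path)) {
    cs <- data.table::fread(cs_path)
    lines <- c(lines, sprintf("%s\t%s", cs$metric, cs$value))
  }
  qc_path <- file.path(outdir, "qc_table.tsv")
  if (file.exists(qc_path)) {
    qc <- data.table::fread(qc_path)
    lines <- c(lines,
               sprintf("cells_kept\t%d", sum(qc$keep)),
               sprintf("doublet_flags\t%d", sum(qc$doublet_flag)),
               sprintf("species_calls\t%s",
                       paste(names(table(qc$species_call)),
                             table(qc$species_call), sep = "=", collapse = ",")))
  }
  amb_path <- file.path(outdir, "ambient_estimate.tsv")
  if (file.exists(amb_path)) lines <- c(lines, readLines(amb_path))
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(lines)
}
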