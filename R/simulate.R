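#' Simulate ground-truth molecule capture on a plate
#'
#' Draws the set of captured mRNA molecules for every well of a plate.
#' Per-cell molecule totals follow a negative-binomial (Gamma-Poisson) law
#' with mean `mean_molecules_per_cell` and dispersion `dispersion`
#' (variance = m + dispersion * m^2).  Gene identities are sampled from
#' log-normal relative-abundance weights fixed per reference; condition
#' effects from `de_spec` multiply a gene's weight by `2^log2fc` in cells
#' carrying that condition.  Every well — including negative controls —
#' additionally receives ambient molecules with expected count
#' `ambient_fraction * mean_molecules_per_cell`, drawn from the pooled
#' two-species abundance profile.  Doublet wells capture two cells' worth
#' of molecules (one cell per species) under a single barcode.  Each
#' molecule is tagged with a UMI drawn uniformly over 7-mers; identical
#' (barcode, gene, UMI) triples are merged, so UMI collisions within a
#' (barcode, gene) pair are possible and left for downstream collapse to
#' handle.
#'
#' @param plate a `PlateDesign` from [design_plate()].
#' @param ref a `ReferenceSet` from [generate_reference()].
#' @param mean_molecules_per_cell expected molecules captured per cell.
#' @param ambient_fraction expected ambient molecules per well as a
#'   fraction of `mean_molecules_per_cell`; in [0, 1).
#' @param de_spec `NULL`, or a data.frame with columns `gene_id`,
#'   `condition`, `log2fc` giving condition-specific fold changes.
#' @param dispersion negative-binomial dispersion of per-cell totals
#'   (0 gives Poisson totals).
#' @param mito_share expected share of a cell's molecules coming from
#'   mitochondrial genes (when the reference has any).
#' @param doublet_ratio relative size of the second cell in a doublet well
#'   (1 = equal mixing).
#' @param umi_length UMI width in bases (default 7).
#' @param seed integer RNG seed.
#' @return A `GroundTruth`: list with `molecules` (data.table: `barcode`,
#'   `gene_id`, `umi`, `source` in cell/ambient), `de_spec`, and the
#'   simulation parameters.
#' @examples
#' ref <- generate_reference(20, 200, seed = 1)
#' plate <- design_plate(4, 4, 2, seed = 1)
#' truth <- simulate_expression(plate, ref, 300, ambient_fraction = 0.05, seed = 1)
#' nrow(truth$molecules)
#' @export
simulate_expression <- function(plate, ref, mean_molecules_per_cell = 5000,
                                ambient_fraction = 0.05, de_spec = NULL,
                                dispersion = 0.1, mito_share = 0.02,
                                doublet_ratio = 1, umi_length = 7, seed = 1) {
  stopifnot(inherits(plate, "PlateDesign"), inherits(ref, "ReferenceSet"))
  if (!is.numeric(mean_molecules_per_cell) || mean_molecules_per_cell <= 0)
    stopf("mean_molecules_per_cell must be positive")
  if (!is.numeric(ambient_fraction) || ambient_fraction < 0 || ambient_fraction >= 1)
    stopf("ambient_fraction must lie in [0, 1)")
  if (!is.numeric(dispersion) || dispersion < 0)
    stopf("dispersion must be non-negative")

  wells <- plate$wells
  genes <- ref$genes
  if (!is.null(de_spec)) {
    de_spec <- data.table::as.data.table(de_spec)
    need <- c("gene_id", "condition", "log2fc")
    if (!all(need %in% names(de_spec)))
      stopf("de_spec needs columns gene_id, condition, log2fc")
    bad_gene <- setdiff(de_spec$gene_id, genes$gene_id)
    if (length(bad_gene) > 0)
      stopf("de_spec references unknown gene(s): %s",
            paste(utils::head(bad_gene, 3), collapse = ", "))
    known_cond <- unique(wells$condition[!is.na(wells$condition)])
    bad_cond <- setdiff(de_spec$condition, known_cond)
    if (length(bad_cond) > 0)
      stopf("de_spec references unknown condition(s): %s",
            paste(utils::head(bad_cond, 3), collapse = ", "))
  }

  with_seed(stage_seed(seed, "expression"), {
    # per-gene baseline relative abundances, log-normal; mitochondrial genes
    # rescaled within each species so they carry mito_share of the mass
    w <- stats::rlnorm(nrow(genes), meanlog = 0, sdlog = 1)
    names(w) <- genes$gene_id
    for (sp in c("A", "B")) {
      sel <- genes$species == sp
      mito <- sel & genes$is_mito
      if (any(mito) && mito_share > 0) {
        w[mito] <- w[mito] / sum(w[mito]) * mito_share * sum(w[sel & !genes$is_mito]) /
          (1 - mito_share)
      } else if (any(mito)) {
        w[mito] <- 0
      }
    }

    cond_weights <- function(cond_label) {
      wc <- w
      if (!is.null(de_spec) && !is.na(cond_label)) {
        rows <- which(de_spec[["condition"]] == cond_label)
        if (length(rows) > 0) {
          idx <- match(de_spec[["gene_id"]][rows], names(wc))
          wc[idx] <- wc[idx] * 2^de_spec[["log2fc"]][rows]
        }
      }
      wc
    }

    draw_total <- function(n, mean) {
      if (dispersion == 0) return(stats::rpois(n, mean))
      lam <- stats::rgamma(n, shape = 1 / dispersion, scale = mean * dispersion)
      stats::rpois(n, lam)
    }

    sample_genes <- function(n, weights) {
      if (n == 0) return(character(0))
      sample(names(weights), n, replace = TRUE, prob = weights)
    }

    bc_out <- character(0); gene_out <- character(0); src_out <- character(0)
    n_wells <- nrow(wells)
    amb_mean <- ambient_fraction * mean_molecules_per_cell
    amb_counts <- if (amb_mean > 0) stats::rpois(n_wells, amb_mean) else
      integer(n_wells)

    for (i in seq_len(n_wells)) {
      kind <- wells$kind[i]
      bc <- wells$barcode[i]
      gs <- character(0)
      if (kind == "cell") {
        wc <- cond_weights(wells$condition[i])
        sel <- genes$species == wells$species[i]
        gs <- sample_genes(draw_total(1, mean_molecules_per_cell), wc[sel])
      } else if (kind == "doublet") {
        wc <- cond_weights(wells$condition[i])
        ga <- sample_genes(draw_total(1, mean_molecules_per_cell),
                           wc[genes$species == "A"])
        gb <- sample_genes(draw_total(1, mean_molecules_per_cell * doublet_ratio),
                           wc[genes$species == "B"])
        gs <- c(ga, gb)
      }
      n_cellmol <- length(gs)
      n_amb <- amb_counts[i]
      if (n_amb > 0) gs <- c(gs, sample_genes(n_amb, w))
      if (length(gs) == 0) next
      bc_out <- c(bc_out, rep(bc, length(gs)))
      gene_out <- c(gene_out, gs)
      src_out <- c(src_out, rep(c("cell", "ambient"), c(n_cellmol, n_amb)))
    }

    mol <- data.table::data.table(barcode = bc_out, gene_id = gene_out,
                                  source = src_out)
    mol$umi <- random_seq(nrow(mol), umi_length)
    # identical triples are one molecule; 'cell' wins over 'ambient' on merge
    data.table::setorder(mol, barcode, gene_id, umi, source)
    mol <- unique(mol, by = c("barcode", "gene_id", "umi"))
    data.table::setcolorder(mol, c("barcode", "gene_id", "umi", "source"))

    structure(list(molecules = mol, de_spec = de_spec,
                   params = list(mean_molecules_per_cell = mean_molecules_per_cell,
                                 ambient_fraction = ambient_fraction,
                                 dispersion = dispersion,
                                 mito_share = mito_share,
                                 doublet_ratio = doublet_ratio,
                                 umi_length = as.integer(umi_length),
                                 seed = seed)),
              class = "GroundTruth")
  })
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d molecules in %d wells (%d ambient)\n",
              nrow(x$molecules), length(unique(x$molecules$barcode)),
              sum(x$molecules$source == "ambient")))
  invisible(x)
}

# Connected components among distinct UMIs at Hamming distance <= 1,
# implemented in plain R (independent of the C++ collapse used by the
# pipeline); used to turn simulated molecules into expected DGE counts.
collapse_components_r <- function(umis) {
  uniq <- unique(umis)
  m <- length(uniq)
  if (m == 0) return(0L)
  if (m == 1) return(1L)
  ch <- do.call(rbind, strsplit(uniq, ""))
  D <- Reduce(`+`, lapply(seq_len(ncol(ch)), function(p)
    outer(ch[, p], ch[, p], `!=`)))
  adj <- D <= 1
  comp <- integer(m)
  n_comp <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    n_comp <- n_comp + 1L
    queue <- s
    comp[s] <- n_comp
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- n_comp
      queue <- c(queue, nb)
    }
  }
  n_comp
}

#' Expected DGE counts implied by a ground truth
#'
#' Collapses the simulated molecule table into the genes-by-cells count
#' matrix a perfect pipeline should recover: per (barcode, gene), the
#' number of Hamming-distance-1 connected components among the molecule
#' UMIs (identical to the pipeline's collapse rule, computed here by an
#' independent plain-R implementation).
#'
#' @param truth a `GroundTruth`.
#' @param ref a `ReferenceSet` (fixes the gene universe and order).
#' @param plate a `PlateDesign` (fixes the cell universe and order).
#' @return a `DGEMatrix` (see [build_dge()]).
#' @export
truth_counts <- function(truth, ref, plate) {
  stopifnot(inherits(truth, "GroundTruth"))
  mol <- truth$molecules
  gene_ids <- sort(ref$genes$gene_id)
  barcodes <- plate$whitelist
  counts <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(length(gene_ids), length(barcodes)),
    dimnames = list(gene_ids, barcodes))
  if (nrow(mol) > 0) {
    grp <- mol[, list(n = collapse_components_r(umi)),
               by = c("barcode", "gene_id")]
    counts <- Matrix::sparseMatrix(
      i = match(grp$gene_id, gene_ids),
      j = match(grp$barcode, barcodes),
      x = grp$n,
      dims = c(length(gene_ids), length(barcodes)),
      dimnames = list(gene_ids, barcodes))
  }
  new_dge(counts)
}

# Apply independent per-base substitution errors to equal-width sequences,
# vectorised in chunks to bound memory.
mutate_seqs <- function(seqs, error_rate, chunk = 200000L) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  width <- unique(nchar(seqs))
  stopifnot(length(width) == 1)
  bases <- c("A", "C", "G", "T")
  for (lo in seq(1, length(seqs), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(seqs))
    m <- matrix(unlist(strsplit(seqs[lo:hi], ""), use.names = FALSE),
                nrow = width)
    err <- which(stats::runif(length(m)) < error_rate)
    if (length(err) > 0) {
      repl <- sample(bases, length(err), replace = TRUE)
      same <- repl == m[err]
      while (any(same)) {
        repl[same] <- sample(bases, sum(same), replace = TRUE)
        same <- repl == m[err]
      }
      m[err] <- repl
      seqs[lo:hi] <- do.call(paste0, asplit(m, 1))
    }
  }
  seqs
}

#' Emit paired FASTQ reads for a simulated ground truth
#'
#' Every molecule is sequenced `k >= 1` times, with `k` drawn from a
#' shifted Poisson with mean `duplication_mean` (PCR duplicates).  Read 1
#' is the 20-bp bead layout: 6-bp cell barcode, 7-bp UMI, then a poly-T pad
#' (the capture oligo continues into its poly-T tail).  Read 2 is a 50-base
#' window of the molecule's transcript taken near the 3' end, with the
#' window start jittered uniformly over the last `window_3prime` bases.
#' Independent per-base substitution errors at `error_rate` are applied to
#' both mates.  Reads are written as gzip-compressed FASTQ with constant
#' base qualities.
#'
#' @param truth a `GroundTruth` from [simulate_expression()].
#' @param ref the `ReferenceSet` the truth was simulated from.
#' @param out_r1,out_r2 output FASTQ paths (".gz" written as gzip).
#' @param duplication_mean mean reads per molecule (>= 1).
#' @param error_rate per-base substitution probability, in [0, 1).
#' @param read2_length Read-2 width (default 50).
#' @param window_3prime jitter range for the Read-2 window start, in bases
#'   from the 3' end.
#' @param seed integer RNG seed.
#' @return list with `n_molecules`, `n_read_pairs`, `r1`, `r2`.
#' @export
simulate_reads <- function(truth, ref, out_r1, out_r2, duplication_mean = 1,
                           error_rate = 0, read2_length = 50,
                           window_3prime = 150, seed = 1) {
  stopifnot(inherits(truth, "GroundTruth"), inherits(ref, "ReferenceSet"))
  if (!is.numeric(duplication_mean) || duplication_mean < 1)
    stopf("duplication_mean must be >= 1")
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1)
    stopf("error_rate must lie in [0, 1)")
  validate_reference(ref, read2_length = read2_length)

  mol <- truth$molecules
  n_mol <- nrow(mol)
  with_seed(stage_seed(seed, "reads"), {
    k <- 1L + stats::rpois(n_mol, max(0, duplication_mean - 1))
    idx <- rep(seq_len(n_mol), k)
    n_reads <- length(idx)

    tx <- ref$seqs[mol$gene_id[idx]]
    L <- nchar(tx)
    max_jit <- pmin(window_3prime, L - read2_length)
    jit <- floor(stats::runif(n_reads) * (max_jit + 1))
    start <- L - read2_length + 1L - jit
    r2 <- substring(tx, start, start + read2_length - 1L)

    pad <- strrep("T", 7)
    r1 <- paste0(mol$barcode[idx], mol$umi[idx], pad)

    r1 <- mutate_seqs(r1, error_rate)
    r2 <- mutate_seqs(r2, error_rate)

    ids <- sprintf("M%07d_%d", idx, sequence(k))
    write_fastq(ids, r1, out_r1)
    write_fastq(ids, r2, out_r2)
    list(n_molecules = n_mol, n_read_pairs = n_reads,
         r1 = out_r1, r2 = out_r2)
  })
}

write_fastq <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, filepath = path,
                              compress = grepl("\\.gz$", path),
                              format = "fastq", qualities = q)
  invisible(path)
}
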