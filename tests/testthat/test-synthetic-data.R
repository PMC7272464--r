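test_that("generate_reference honours counts, mito floor rule and determinism", {
  ref <- generate_reference(2, 100, mito_fraction = 0, seed = 1)
  expect_equal(nrow(ref$genes), 4)
  expect_equal(as.vector(table(ref$genes$species)), c(2, 2))
  expect_false(any(ref$genes$is_mito))
  expect_true(all(nchar(ref$seqs) == 100))

  # floor(n * fraction) mitochondrial genes per species
  ref2 <- generate_reference(10, 100, mito_fraction = 0.2, seed = 7)
  expect_equal(sum(ref2$genes$is_mito & ref2$genes$species == "A"), 2)
  expect_equal(sum(ref2$genes$is_mito & ref2$genes$species == "B"), 2)
  # at least one mito gene per species whenever the fraction is positive
  ref3 <- generate_reference(5, 100, mito_fraction = 0.1, seed = 2)
  expect_equal(sum(ref3$genes$is_mito & ref3$genes$species == "A"), 1)

  expect_identical(generate_reference(10, 100, 0.2, seed = 1),
                   generate_reference(10, 100, 0.2, seed = 1))
  expect_false(identical(generate_reference(10, 100, 0.2, seed = 1)$seqs,
                         generate_reference(10, 100, 0.2, seed = 2)$seqs))

  expect_error(generate_reference(1, 100), "n_genes_per_species")
  expect_error(generate_reference(5, 10), "transcript_length")
  expect_error(generate_reference(5, 100, mito_fraction = 1), "mito_fraction")
})

test_that("gene ids are unique and carry their species prefix", {
  ref <- generate_reference(25, 120, mito_fraction = 0.2, seed = 3)
  expect_false(anyDuplicated(ref$genes$gene_id) > 0)
  expect_true(all(startsWith(ref$genes$gene_id[ref$genes$species == "A"], "HUM_")))
  expect_true(all(startsWith(ref$genes$gene_id[ref$genes$species == "B"], "MUS_")))
})

test_that("design_plate produces the right well mix and whitelist distances", {
  plate <- design_plate(96, 96, 32, 0, seed = 1)
  expect_equal(nrow(plate$wells), 224)
  expect_equal(sum(plate$wells$kind == "cell"), 192)
  expect_equal(sum(plate$wells$kind == "negative"), 32)
  expect_true(all(is.na(plate$wells$species[plate$wells$kind == "negative"])))
  expect_false(anyDuplicated(plate$whitelist) > 0)

  # exhaustive pairwise distance scan respects the requested minimum
  for (md in c(2, 3)) {
    wl <- design_plate(10, 10, 4, 0, seed = 5, min_distance = md)$whitelist
    pairs <- combn(length(wl), 2)
    d <- apply(pairs, 2, function(p) hamming_distance(wl[p[1]], wl[p[2]]))
    expect_true(all(d >= md), label = sprintf("min distance %d", md))
  }

  two <- design_plate(1, 0, 0, 1, seed = 2, min_distance = 3)
  expect_equal(nrow(two$wells), 2)
  expect_gte(hamming_distance(two$whitelist[1], two$whitelist[2]), 3)
  expect_equal(two$wells$species[two$wells$kind == "doublet"], "A+B")
})

test_that("whitelist construction fails loudly when the code cannot exist", {
  expect_error(make_whitelist(300, barcode_length = 6, min_distance = 3,
                              max_restarts = 2),
               "Hamming")
})

test_that("condition labels cover cell wells round-robin", {
  plate <- design_plate(8, 0, 2, 0, conditions = c("drug", "dmso", "dmso", "dmso"),
                        seed = 4)
  cond <- plate$wells$condition[plate$wells$kind == "cell"]
  expect_equal(sum(cond == "drug"), 2)
  expect_equal(sum(cond == "dmso"), 6)
  expect_true(all(is.na(plate$wells$condition[plate$wells$kind == "negative"])))
})

test_that("simulate_expression zero cases and validation", {
  ref <- mini_ref()
  plate <- mini_plate(4, 4, 2)
  truth0 <- simulate_expression(plate, ref, 200, ambient_fraction = 0, seed = 1)
  neg_bc <- plate$wells$barcode[plate$wells$kind == "negative"]
  expect_equal(sum(truth0$molecules$barcode %in% neg_bc), 0)
  expect_false(anyDuplicated(truth0$molecules[, c("barcode", "gene_id", "umi")]) > 0)

  expect_error(simulate_expression(plate, ref, 200, de_spec = data.frame(
    gene_id = "NOPE", condition = "x", log2fc = 1)), "unknown gene")
  pl2 <- mini_plate(4, 4, 2, conditions = c("a", "b"))
  expect_error(simulate_expression(pl2, ref, 200, de_spec = data.frame(
    gene_id = ref$genes$gene_id[1], condition = "zzz", log2fc = 1)),
    "unknown condition")
  expect_error(simulate_expression(plate, ref, 200, ambient_fraction = 1),
               "ambient_fraction")
})

test_that("with no effect table all conditions share one expression law", {
  ref <- mini_ref(n = 30, seed = 7)
  plate <- design_plate(60, 0, 0, 0, conditions = c("x", "y"), seed = 7)
  truth <- simulate_expression(plate, ref, 400, ambient_fraction = 0,
                               dispersion = 0, seed = 7)
  mol <- truth$molecules
  cond <- plate$wells$condition[match(mol$barcode, plate$wells$barcode)]
  shares <- prop.table(table(mol$gene_id, cond), margin = 2)
  # same sampling law in both arms: per-gene shares agree closely
  expect_lt(max(abs(shares[, "x"] - shares[, "y"])), 0.02)
})

test_that("ambient molecules land in negative wells at the configured rate", {
  ref <- mini_ref(n = 50, seed = 9)
  plate <- design_plate(40, 40, 16, 0, seed = 9)
  af <- 0.05
  truth <- simulate_expression(plate, ref, 1000, ambient_fraction = af,
                               dispersion = 0.1, seed = 9)
  mol <- truth$molecules
  kind <- plate$wells$kind[match(mol$barcode, plate$wells$barcode)]
  neg_bc <- plate$wells$barcode[plate$wells$kind == "negative"]
  neg_counts <- table(factor(mol$barcode[kind == "negative"], levels = neg_bc))
  cell_bc <- plate$wells$barcode[plate$wells$kind == "cell"]
  cell_counts <- table(factor(mol$barcode[kind == "cell"], levels = cell_bc))
  ratio <- mean(neg_counts) / mean(cell_counts)
  # negative wells hold ambient only; cells hold own + ambient molecules
  target <- af / (1 + af)
  se <- sqrt(target * (1 - target) / (af * 1000 * length(neg_bc)))
  expect_lt(abs(ratio - target), 3 * se + 0.005)
  # ambient source labels never appear only in one species' wells
  amb <- mol[mol$source == "ambient", ]
  expect_true(any(amb$barcode %in% neg_bc))
})

test_that("read layout matches the bead design and zero-noise reads are exact", {
  run <- mini_run(dup = 1, err = 0, mean_mol = 150)
  fq1 <- read_fastq_plain(run$r1)
  fq2 <- read_fastq_plain(run$r2)
  # duplication mean 1, error 0: one read pair per molecule
  expect_equal(length(fq1$seq), nrow(run$truth$molecules))
  expect_equal(run$reads$n_read_pairs, run$reads$n_molecules)
  expect_true(all(nchar(fq1$seq) == 20))
  expect_true(all(nchar(fq2$seq) == 50))

  mol <- run$truth$molecules
  ord <- as.integer(sub("M0*([0-9]+)_.*", "\\1", fq1$id))
  # bases 1-6 are the well barcode, 7-13 the UMI, 14-20 poly-T pad
  expect_equal(substr(fq1$seq, 1, 6), mol$barcode[ord])
  expect_equal(substr(fq1$seq, 7, 13), mol$umi[ord])
  expect_true(all(substr(fq1$seq, 14, 20) == "TTTTTTT"))
  # every Read 2 is an exact substring of its source transcript
  tx <- run$ref$seqs[mol$gene_id[ord]]
  hits <- mapply(function(r, t) grepl(r, t, fixed = TRUE), fq2$seq, tx)
  expect_true(all(hits))
})

test_that("read simulation is deterministic and duplication shifts the pair count", {
  run <- mini_run(dup = 3, err = 0, mean_mol = 100, seed = 77)
  expect_gte(run$reads$n_read_pairs, run$reads$n_molecules)
  r1b <- tempfile(fileext = ".fastq.gz")
  r2b <- tempfile(fileext = ".fastq.gz")
  simulate_reads(run$truth, run$ref, r1b, r2b, duplication_mean = 3,
                 error_rate = 0, seed = 77)
  expect_identical(read_fastq_plain(run$r1), read_fastq_plain(r1b))
  expect_identical(read_fastq_plain(run$r2), read_fastq_plain(r2b))
  expect_error(simulate_reads(run$truth, run$ref, r1b, r2b,
                              duplication_mean = 0.5), "duplication_mean")
})

test_that("doublet wells mix two species under one barcode", {
  ref <- mini_ref(n = 30, seed = 13)
  plate <- mini_plate(4, 4, 1, dbl = 2, seed = 13)
  truth <- simulate_expression(plate, ref, 400, ambient_fraction = 0, seed = 13)
  dbl_bc <- plate$wells$barcode[plate$wells$kind == "doublet"]
  for (bc in dbl_bc) {
    gs <- truth$molecules$gene_id[truth$molecules$barcode == bc]
    sp <- ref$genes$species[match(gs, ref$genes$gene_id)]
    expect_setequal(unique(sp), c("A", "B"))
    # roughly 1:1 mixing
    expect_gt(mean(sp == "A"), 0.25)
    expect_lt(mean(sp == "A"), 0.75)
  }
})
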