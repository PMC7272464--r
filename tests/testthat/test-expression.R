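norm_fixture <- function(n_genes = 50, n_cells = 30, seed = 71) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_cells, 20), n_genes, n_cells,
                   dimnames = list(sprintf("HUM_G%03d", seq_len(n_genes)),
                                   sprintf("BC%03d", seq_len(n_cells))))
  cpm_log_normalize(as_dge(Matrix::Matrix(counts, sparse = TRUE)))
}

test_that("cpm_log_normalize matches direct arithmetic and inverts exactly", {
  counts <- Matrix::Matrix(c(10, 0, 3, 1), 2, 2, sparse = TRUE,
                           dimnames = list(c("g1", "g2"), c("c1", "c2")))
  norm <- cpm_log_normalize(as_dge(counts))
  expect_equal(norm["g1", "c1"], log2(1e6 + 1), tolerance = 1e-10)
  expect_equal(norm["g1", "c1"], 19.9316, tolerance = 1e-4)
  expect_equal(norm["g2", "c1"], 0)
  # inversion identity: each cell's CPM sums back to exactly 1e6
  inv <- 2^norm - 1
  expect_equal(colSums(inv), c(c1 = 1e6, c2 = 1e6), tolerance = 1e-6)

  uniform <- Matrix::Matrix(matrix(1, 4, 1,
                                   dimnames = list(letters[1:4], "c")),
                            sparse = TRUE)
  nu <- cpm_log_normalize(as_dge(uniform))
  expect_equal(length(unique(round(nu[, 1], 12))), 1)

  zero <- Matrix::Matrix(c(1, 0), 1, 2, sparse = TRUE,
                         dimnames = list("g", c("ok", "empty")))
  expect_error(cpm_log_normalize(as_dge(zero)), "empty")
})

test_that("select_variable_genes ranks a planted high-variance gene first", {
  set.seed(72)
  counts <- matrix(5, 40, 30,
                   dimnames = list(sprintf("g%02d", 1:40),
                                   sprintf("c%02d", 1:30)))
  counts["g07", ] <- sample(c(0, 60), 30, replace = TRUE)
  norm <- cpm_log_normalize(as_dge(Matrix::Matrix(counts, sparse = TRUE)))
  expect_equal(select_variable_genes(norm, 1), "g07")
  expect_setequal(select_variable_genes(norm, 40), rownames(norm))
  expect_error(select_variable_genes(norm, 41), "exceeds")
})

test_that("variable-gene selection finds most planted DE genes", {
  ref <- generate_reference(150, 300, seed = 73)
  genes_a <- ref$genes$gene_id[ref$genes$species == "A"]
  set.seed(73)
  planted <- sample(genes_a, 50)
  plate <- design_plate(60, 0, 0, 0, conditions = c("x", "y"), seed = 73)
  de_spec <- data.frame(gene_id = planted, condition = "y", log2fc = 2.5)
  truth <- simulate_expression(plate, ref, 4000, ambient_fraction = 0,
                               de_spec = de_spec, dispersion = 0.05, seed = 73)
  dge <- truth_counts(truth, ref, plate)
  keep <- Matrix::colSums(dge$counts) > 0
  norm <- cpm_log_normalize(as_dge(dge$counts[, keep]))
  top <- select_variable_genes(norm, 200)
  expect_gte(mean(planted %in% top), 0.8)
})

test_that("run_pca is deterministic, ordered, and matches an eigen oracle", {
  set.seed(74)
  # planted dominant axis
  scores <- rnorm(40, sd = 8)
  base <- outer(rnorm(20), scores) + matrix(rnorm(800, sd = 0.5), 20, 40)
  dimnames(base) <- list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:40))
  p <- run_pca(base, n_pcs = 4)
  expect_gt(p$var_explained[1], max(p$var_explained[-1]))
  expect_equal(dim(p$embedding), c(40L, 4L))
  expect_identical(p$embedding, run_pca(base, n_pcs = 4)$embedding)

  # orthogonal rotation of the gene axes leaves explained variances unchanged
  q <- qr.Q(qr(matrix(rnorm(400), 20, 20)))
  rot <- q %*% base
  dimnames(rot) <- dimnames(base)
  p2 <- run_pca(rot, n_pcs = 4)
  expect_equal(p2$sdev, p$sdev, tolerance = 1e-8)

  # independent linear-algebra oracle on a 5 x 4 fixture
  m <- matrix(c(1, 3, 5, 2, 4,
                2, 2, 1, 0, 7,
                5, 1, 0, 2, 2,
                1, 1, 3, 3, 3), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  pr <- run_pca(m, n_pcs = 3)
  centred <- t(m - rowMeans(m))
  ev <- eigen(crossprod(centred) / (nrow(centred) - 1))
  emb_oracle <- centred %*% ev$vectors[, 1:3]
  for (j in 1:3) {
    expect_equal(abs(pr$embedding[, j]), abs(emb_oracle[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(run_pca(m, n_pcs = 5), "at least")
})

test_that("cluster_cells recovers well-separated blobs and handles degenerate input", {
  set.seed(75)
  emb <- rbind(matrix(rnorm(240, 0), ncol = 4), matrix(rnorm(240, 7), ncol = 4))
  labels <- rep(0:1, each = 60)
  cl <- cluster_cells(emb, resolution = 0.8, seed = 1)
  expect_equal(length(unique(cl)), 2)
  expect_equal(adjusted_rand_index(cl, labels), 1)
  expect_setequal(unique(cl), 0:1)
  # deterministic under a fixed seed
  expect_identical(cl, cluster_cells(emb, resolution = 0.8, seed = 1))

  expect_equal(cluster_cells(matrix(0, 1, 2)), 0L)
  expect_warning(one <- cluster_cells(matrix(1, 5, 2)), "identical")
  expect_equal(one, rep(0L, 5))
})

test_that("rank_sum_test equals exact permutation enumeration up to n = 8", {
  set.seed(76)
  perm_oracle <- function(x, y) {
    v <- c(x, y); nx <- length(x)
    r <- rank(v)
    mu <- nx * (length(v) + 1) / 2
    obs <- abs(sum(r[seq_len(nx)]) - mu)
    sets <- combn(length(v), nx)
    stat <- apply(sets, 2, function(ix) abs(sum(r[ix]) - mu))
    mean(stat >= obs - 1e-9)
  }
  for (rep in 1:25) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- sample(0:5, nx, replace = TRUE)  # ties on purpose
    y <- sample(0:5, ny, replace = TRUE)
    expect_equal(rank_sum_test(x, y), perm_oracle(x, y),
                 label = sprintf("rep %d", rep))
  }
  # identical groups: p = 1
  z <- c(1, 2, 3, 4)
  expect_equal(rank_sum_test(z, z), 1)
})

test_that("large-sample path agrees with wilcox.test's corrected approximation", {
  set.seed(77)
  for (rep in 1:10) {
    x <- rnorm(25); y <- rnorm(30, 0.4)
    ours <- rank_sum_test(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  # with heavy ties the tie-corrected variance matches too
  x <- sample(0:3, 40, replace = TRUE)
  y <- sample(0:3, 35, replace = TRUE)
  expect_equal(rank_sum_test(x, y),
               suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value),
               tolerance = 1e-10)
})

test_that("wilcoxon_de labels directions by the volcano rule and BH is monotone", {
  set.seed(78)
  norm <- norm_fixture(n_genes = 60, n_cells = 40)
  a <- colnames(norm)[1:20]; b <- colnames(norm)[21:40]
  de <- wilcoxon_de(norm, a, b)
  expect_true(all(de$fdr >= de$p_value - 1e-12))
  ord <- order(de$p_value)
  expect_true(all(diff(de$fdr[ord]) >= -1e-12))
  expect_identical(de$fdr, p.adjust(de$p_value, "BH"))
  lab <- ifelse(de$fdr < 0.05 & de$log2fc > 0.25, "up",
                ifelse(de$fdr < 0.05 & de$log2fc < -0.25, "down", "ns"))
  expect_identical(de$direction, lab)

  # identical groups: everything null
  de0 <- wilcoxon_de(cbind(norm[, a], norm[, a][, 1:20]),
                     a, colnames(norm)[1:20])
  expect_true(all(de0$direction == "ns"))
  expect_true(all(abs(de0$log2fc) < 1e-12))
  expect_error(wilcoxon_de(norm, a[1], b), "at least 2")
})

test_that("type-I error at alpha 0.05 sits within 3 binomial SE on null genes", {
  set.seed(79)
  n_genes <- 5000
  vals <- matrix(rpois(n_genes * 40, 15), n_genes, 40,
                 dimnames = list(sprintf("g%04d", 1:n_genes),
                                 sprintf("c%02d", 1:40)))
  norm <- cpm_log_normalize(as_dge(Matrix::Matrix(vals, sparse = TRUE)))
  de <- wilcoxon_de(norm, colnames(norm)[1:20], colnames(norm)[21:40])
  rate <- mean(de$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / n_genes)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("cell-cycle scoring follows the argmax rule and recovers planted phases", {
  set.seed(80)
  genes <- sprintf("g%03d", 1:300)
  s_mark <- genes[1:15]; g2m_mark <- genes[16:30]
  # varied baseline expression so expression-matched backgrounds exist
  lambda <- rlnorm(300, meanlog = log(30), sdlog = 1)
  counts <- matrix(rpois(300 * 60, rep(lambda, 60)), 300, 60,
                   dimnames = list(genes, sprintf("c%02d", 1:60)))
  phase_true <- rep(c("G1", "S", "G2M"), each = 20)
  counts[s_mark, phase_true == "S"] <- counts[s_mark, phase_true == "S"] * 4
  counts[g2m_mark, phase_true == "G2M"] <- counts[g2m_mark, phase_true == "G2M"] * 4
  norm <- cpm_log_normalize(as_dge(Matrix::Matrix(counts, sparse = TRUE)))
  cc <- score_cell_cycle(norm, s_mark, g2m_mark, seed = 3)
  expect_gte(mean(cc$phase == phase_true), 0.9)

  # no marker expression at all: G1 by default
  cold <- counts
  cold[c(s_mark, g2m_mark), ] <- 0
  cc0 <- score_cell_cycle(cpm_log_normalize(as_dge(Matrix::Matrix(cold, sparse = TRUE))),
                          s_mark, g2m_mark, seed = 3)
  expect_true(all(cc0$phase == "G1"))
  expect_error(score_cell_cycle(norm, c("nope1", "nope2"), g2m_mark), "missing")
  expect_warning(score_cell_cycle(norm, c(s_mark, "nope"), g2m_mark), "dropped")
})

test_that("remove_batch_effect removes additive offsets exactly and matches limma", {
  set.seed(81)
  norm <- norm_fixture(n_genes = 40, n_cells = 24)
  batch <- rep(c("b1", "b2"), each = 12)
  offset <- rnorm(40, sd = 2)
  shifted <- norm
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + offset
  adj <- remove_batch_effect(shifted, batch)
  expect_equal(rowMeans(adj[, batch == "b1"]), rowMeans(adj[, batch == "b2"]),
               tolerance = 1e-10)

  # single batch: identity
  expect_identical(remove_batch_effect(norm, rep("b1", 24)), norm)

  # perfectly confounded design is rejected with the aliasing named
  cond <- ifelse(batch == "b1", "ctrl", "drug")
  expect_error(remove_batch_effect(shifted, batch, cond), "aliased")

  # equivalence with limma's linear-model batch removal
  skip_if_not_installed("limma")
  cond2 <- rep(c("ctrl", "drug"), 12)
  adj_ours <- remove_batch_effect(shifted, batch, cond2)
  design <- stats::model.matrix(~factor(cond2))
  adj_limma <- limma::removeBatchEffect(shifted, batch = batch, design = design)
  expect_equal(adj_ours, adj_limma, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("pseudobulk profiles and correlations behave at the extremes", {
  norm <- norm_fixture(n_genes = 200, n_cells = 20)
  cond <- rep(c("x", "y"), each = 10)
  # duplicate conditions built from the same cells correlate perfectly
  dup <- cbind(norm[, 1:10], norm[, 1:10])
  colnames(dup) <- sprintf("c%02d", 1:20)
  pb <- pseudobulk_profiles(dup, cond)
  expect_equal(pb$r["x", "y"], 1, tolerance = 1e-12)
  expect_equal(pb$r2["x", "y"], 1, tolerance = 1e-12)

  # independent random profiles decorrelate
  set.seed(82)
  big <- matrix(rnorm(5000 * 2), 5000, 2,
                dimnames = list(sprintf("g%04d", 1:5000), c("c1", "c2")))
  pb2 <- pseudobulk_profiles(big, c("p", "q"))
  expect_lt(abs(pb2$r["p", "q"]), 0.1)

  expect_error(pseudobulk_profiles(norm, factor(rep("x", 20),
                                                levels = c("x", "ghost"))),
               "zero cells")
})

test_that("heatmap gene set is the union of per-contrast significant genes", {
  mk <- function(genes, fdr, lfc) data.table::data.table(
    gene_id = genes, p_value = fdr, fdr = fdr, log2fc = lfc,
    direction = "ns")
  null1 <- mk(c("g1", "g2"), c(0.9, 0.8), c(0, 0))
  null2 <- mk(c("g2", "g3"), c(0.7, 0.6), c(0, 0))
  expect_equal(heatmap_gene_set(list(a = null1, b = null2))$genes, character(0))

  one <- mk(c("g1", "g2"), c(0.001, 0.9), c(1, 0))
  hs <- heatmap_gene_set(list(a = one, b = null2))
  expect_equal(hs$genes, "g1")
  expect_equal(hs$lfc["g1", "a"], 1)
  expect_true(is.na(hs$lfc["g1", "b"]))

  # brute-force set union over overlapping planted contrasts
  set.seed(83)
  contrasts <- lapply(1:3, function(i) {
    genes <- sprintf("g%02d", 1:40)
    fdr <- runif(40)
    fdr[sample(40, 10)] <- 0.001
    mk(genes, fdr, rnorm(40))
  })
  names(contrasts) <- c("d1", "d2", "d3")
  expected <- sort(Reduce(union, lapply(contrasts, function(d)
    d$gene_id[d$fdr < 0.05])))
  expect_equal(heatmap_gene_set(contrasts)$genes, expected)
})
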