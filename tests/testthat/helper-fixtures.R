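# Shared fixtures, built in code at test time.

mini_ref <- function(n = 20, len = 200, mito = 0.1, seed = 101) {
  generate_reference(n, len, mito_fraction = mito, seed = seed)
}

mini_plate <- function(a = 6, b = 6, neg = 3, dbl = 0, conditions = character(),
                       seed = 101, min_distance = 3) {
  design_plate(a, b, neg, dbl, conditions, seed = seed,
               min_distance = min_distance)
}

# simulate a small plate end to end and return all of the pieces
mini_run <- function(a = 6, b = 6, neg = 3, dbl = 0, mean_mol = 300,
                     ambient = 0, dup = 2, err = 0, seed = 101,
                     conditions = character(), dispersion = 0.1) {
  ref <- mini_ref(seed = seed)
  plate <- mini_plate(a, b, neg, dbl, conditions, seed = seed)
  truth <- simulate_expression(plate, ref, mean_mol, ambient_fraction = ambient,
                               dispersion = dispersion, seed = seed)
  r1 <- tempfile(fileext = ".fastq.gz")
  r2 <- tempfile(fileext = ".fastq.gz")
  reads <- simulate_reads(truth, ref, r1, r2, duplication_mean = dup,
                          error_rate = err, seed = seed)
  list(ref = ref, plate = plate, truth = truth, r1 = r1, r2 = r2,
       reads = reads)
}

# plain-R reference implementation of pairwise Hamming distance
hamming_ref <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force union-find molecule count over a UMI multiset: all-pairs
# position-wise distance matrix, then union every pair at distance <= 1
collapse_oracle <- function(umis) {
  u <- unique(umis)
  m <- length(u)
  if (m == 0) return(0L)
  ch <- do.call(rbind, strsplit(u, ""))
  D <- matrix(0L, m, m)
  for (p in seq_len(ncol(ch))) D <- D + outer(ch[, p], ch[, p], `!=`)
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i < j && D[i, j] <= 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(m), find, integer(1))))
}

# read a 4-line-record FASTQ (possibly gzipped) without Biostrings
read_fastq_plain <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  list(id = sub("^@", "", lines[seq(1, length(lines), 4)]),
       seq = lines[seq(2, length(lines), 4)])
}

adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  (a - expected) / ((b + c) / 2 - expected)
}
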