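#' Build a barcode whitelist with a minimum pairwise Hamming distance
#'
#' Greedy maximal-code construction: all `4^length` barcodes are visited in
#' a seeded random order and kept when they respect the minimum pairwise
#' distance against every barcode already chosen.  Construction restarts
#' with a fresh order a bounded number of times before failing.
#'
#' A distance-3 code makes every single-substitution error uniquely
#' correctable, but 6-mer codes at distance 3 cannot exceed 215 barcodes
#' (sphere packing: 4096 / 19) and greedy search finds about 90, so large
#' plates use distance 2: correction is then still safe (a barcode one
#' substitution away from its well is either rescued or rejected as
#' ambiguous, never reassigned to a different well), at the cost of some
#' rescues being rejected.
#'
#' @param n number of barcodes required.
#' @param barcode_length barcode width in bases (default 6).
#' @param min_distance minimum pairwise Hamming distance (default 2).
#' @param seed integer RNG seed.
#' @param max_restarts restarts before giving up.
#' @return character vector of `n` barcodes.
#' @examples
#' wl <- make_whitelist(48, min_distance = 3, seed = 1)
#' min(utils::combn(seq_along(wl), 2, function(i) hamming_distance(wl[i[1]], wl[i[2]])))
#' @export
make_whitelist <- function(n, barcode_length = 6, min_distance = 2, seed = 1,
                           max_restarts = 20) {
  if (!is_count(n, min = 1)) stopf("n must be a positive integer")
  if (!is_count(barcode_length, min = 2)) stopf("barcode_length must be >= 2")
  if (!is_count(min_distance, min = 1) || min_distance > barcode_length)
    stopf("min_distance must be in 1..barcode_length")
  if (n > 4^barcode_length)
    stopf("whitelist constraint unsatisfiable: %d barcodes requested from a space of %d",
          n, 4^barcode_length)

  space <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")),
                                           barcode_length),
                                       stringsAsFactors = FALSE))
  mat_all <- do.call(rbind, strsplit(space, ""))

  for (attempt in seq_len(max_restarts)) {
    chosen <- with_seed(stage_seed(seed, paste0("whitelist", attempt)), {
      ord <- sample(length(space))
      kept <- integer(0)
      kept_mat <- matrix(character(0), ncol = barcode_length)
      for (i in ord) {
        ok <- TRUE
        if (length(kept) > 0) {
          d <- rowSums(kept_mat != matrix(mat_all[i, ], nrow = length(kept),
                                          ncol = barcode_length, byrow = TRUE))
          ok <- all(d >= min_distance)
        }
        if (ok) {
          kept <- c(kept, i)
          kept_mat <- rbind(kept_mat, mat_all[i, ])
          if (length(kept) == n) break
        }
      }
      kept
    })
    if (length(chosen) == n) return(space[chosen])
  }
  stopf(paste0("whitelist construction failed: could not find %d barcodes of ",
               "length %d with pairwise Hamming distance >= %d after %d restarts"),
        n, barcode_length, min_distance, max_restarts)
}

#' Design a two-species barnyard plate
#'
#' Lays out a microwell plate for a species-mixing experiment: cell wells
#' for each of two species, negative-control wells that receive a bead but
#' no cell, and optional doublet wells in which two cells (one per species)
#' share a barcode.  Each well gets a unique barcode from a whitelist built
#' by [make_whitelist()].  Cell wells are assigned condition labels (e.g.
#' drug treatments) round-robin when `conditions` is non-empty.
#'
#' The default geometry matches a validation plate of 96 + 96 cell wells
#' plus 32 negative-control wells (224 wells in total).
#'
#' @param n_cells_a,n_cells_b cell wells per species.
#' @param n_negative negative-control wells (no cell, bead only).
#' @param n_doublets wells holding one cell of each species.
#' @param conditions character vector of condition labels for cell wells
#'   (empty for none).
#' @param seed integer RNG seed.
#' @param barcode_length,min_distance whitelist parameters; see
#'   [make_whitelist()].
#' @return A `PlateDesign`: list with `wells` (data.table: `well_id`,
#'   `barcode`, `kind` in cell/negative/doublet, `species` in
#'   A/B/`A+B`/`NA`, `condition`) and `whitelist`.
#' @examples
#' plate <- design_plate(4, 4, 2, seed = 1)
#' table(plate$wells$kind)
#' @export
design_plate <- function(n_cells_a = 96, n_cells_b = 96, n_negative = 32,
                         n_doublets = 0, conditions = character(), seed = 1,
                         barcode_length = 6, min_distance = 2) {
  for (arg in list(n_cells_a, n_cells_b, n_negative, n_doublets))
    if (!is_count(arg)) stopf("well counts must be non-negative integers")
  n_wells <- n_cells_a + n_cells_b + n_negative + n_doublets
  if (n_wells < 1) stopf("plate must contain at least one well")

  whitelist <- make_whitelist(n_wells, barcode_length = barcode_length,
                              min_distance = min_distance, seed = seed)
  kind <- c(rep("cell", n_cells_a + n_cells_b),
            rep("negative", n_negative),
            rep("doublet", n_doublets))
  species <- c(rep("A", n_cells_a), rep("B", n_cells_b),
               rep(NA_character_, n_negative),
               rep("A+B", n_doublets))
  condition <- rep(NA_character_, n_wells)
  if (length(conditions) > 0) {
    idx <- which(kind != "negative")
    condition[idx] <- rep_len(as.character(conditions), length(idx))
  }
  wells <- data.table::data.table(
    well_id = sprintf("W%03d", seq_len(n_wells)),
    barcode = whitelist,
    kind = kind,
    species = species,
    condition = condition
  )
  structure(list(wells = wells, whitelist = whitelist,
                 min_distance = as.integer(min_distance),
                 barcode_length = as.integer(barcode_length)),
            class = "PlateDesign")
}

#' @export
print.PlateDesign <- function(x, ...) {
  k <- table(x$wells$kind)
  cat(sprintf("PlateDesign: %d wells (%s); barcode length %d, min pairwise Hamming %d\n",
              nrow(x$wells),
              paste(sprintf("%d %s", as.integer(k), names(k)), collapse = ", "),
              x$barcode_length, x$min_distance))
  invisible(x)
}

#' Write / read a plate design as a tab-separated table
#'
#' @param plate a `PlateDesign`.
#' @param path TSV path.
#' @export
write_plate <- function(plate, path) {
  stopifnot(inherits(plate, "PlateDesign"))
  utils::write.table(plate$wells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path) {
  wells <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("well_id", "barcode", "kind", "species", "condition")))
  wells[wells$species == "", "species"] <- NA_character_
  wells[wells$condition == "", "condition"] <- NA_character_
  bl <- unique(nchar(wells$barcode))
  if (length(bl) != 1) stopf("plate file mixes barcode lengths")
  n <- nrow(wells)
  mind <- bl
  if (n > 1) {
    mat <- do.call(rbind, strsplit(wells$barcode, ""))
    dmin <- bl
    for (i in seq_len(n - 1)) {
      d <- rowSums(mat[(i + 1):n, , drop = FALSE] !=
                     matrix(mat[i, ], n - i, bl, byrow = TRUE))
      dmin <- min(dmin, d)
    }
    mind <- dmin
  }
  structure(list(wells = wells, whitelist = wells$barcode,
                 min_distance = as.integer(mind),
                 barcode_length = as.integer(bl)),
            class = "PlateDesign")
}
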