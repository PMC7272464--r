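#' Parse Read 1 into cell barcode and UMI
#'
#' Read 1 of the bead layout carries the 6-bp cell barcode in bases 1-6 and
#' the 7-bp UMI in bases 7-13; everything beyond base 13 (the poly-T pad)
#' is ignored.  Parsing is purely positional.
#'
#' @param seq character vector of Read-1 sequences.
#' @param barcode_length,umi_length layout widths (defaults 6 and 7).
#' @return data.table with columns `barcode`, `umi`, and logical
#'   `malformed` (read shorter than barcode + UMI; its barcode/umi are NA).
#' @examples
#' parse_read1("ACGTACAACCGGGTTTTTTT")
#' @export
parse_read1 <- function(seq, barcode_length = 6, umi_length = 7) {
  need <- barcode_length + umi_length
  malformed <- nchar(seq) < need
  barcode <- ifelse(malformed, NA_character_, substr(seq, 1, barcode_length))
  umi <- ifelse(malformed, NA_character_,
                substr(seq, barcode_length + 1, need))
  data.table::data.table(barcode = barcode, umi = umi, malformed = malformed)
}

#' Correct an observed barcode against a whitelist
#'
#' An exact whitelist member is returned as is.  Otherwise, if exactly one
#' whitelist member lies at Hamming distance 1 the observed barcode is
#' corrected to it; with two or more candidates the read is rejected as
#' ambiguous, with none as no-match.  `N` counts as a mismatch.
#'
#' @param observed a single barcode string.
#' @param whitelist character vector of whitelist barcodes.
#' @return list with `barcode` (whitelist member or `NA`) and `status`, one
#'   of `"exact"`, `"corrected"`, `"ambiguous"`, `"no_match"`.
#' @examples
#' correct_barcode("AAAAAT", c("AAAAAA", "CCCCCC"))
#' @export
correct_barcode <- function(observed, whitelist) {
  stopifnot(length(observed) == 1)
  hit <- cpp_match_barcodes(observed, whitelist)
  if (hit > 0) {
    status <- if (observed == whitelist[hit]) "exact" else "corrected"
    list(barcode = whitelist[hit], status = status)
  } else {
    list(barcode = NA_character_,
         status = if (hit == 0) "no_match" else "ambiguous")
  }
}

#' Tag a pair of FASTQ files with barcodes and UMIs
#'
#' Streams a Read-1/Read-2 FASTQ pair, parses each Read 1 into barcode and
#' UMI, corrects barcodes against the whitelist (exact match, else unique
#' Hamming-1 neighbour), and returns the accepted tagged reads together
#' with disjoint rejection counts.  The two files must be record-paired.
#'
#' @param r1_path,r2_path FASTQ paths (plain or gzip).
#' @param whitelist character vector of well barcodes.
#' @param barcode_length,umi_length Read-1 layout widths.
#' @return list with `tags` (data.table: `barcode` — whitelist member after
#'   correction, `umi`, `read2`) and `stats`, a named integer vector with
#'   `n_total`, `n_exact`, `n_corrected`, `n_ambiguous`, `n_no_match`,
#'   `n_malformed` (categories are disjoint and sum to `n_total`).
#' @export
tag_reads <- function(r1_path, r2_path, whitelist, barcode_length = 6,
                      umi_length = 7) {
  r1 <- as.character(Biostrings::readDNAStringSet(r1_path, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(r2_path, format = "fastq"))
  if (length(r1) != length(r2))
    stopf("unpaired FASTQ input: %d Read-1 records vs %d Read-2 records",
          length(r1), length(r2))

  n_total <- length(r1)
  parsed <- parse_read1(r1, barcode_length, umi_length)
  ok <- !parsed$malformed

  status <- integer(0)
  if (any(ok)) {
    # correct unique observed barcodes once, then map back
    obs <- parsed$barcode[ok]
    uo <- unique(obs)
    hit_u <- cpp_match_barcodes(uo, whitelist)
    hit <- hit_u[match(obs, uo)]
    status <- hit
  }

  accepted_idx <- which(ok)[status > 0]
  corrected_bc <- whitelist[status[status > 0]]
  exact <- corrected_bc == parsed$barcode[accepted_idx]

  tags <- data.table::data.table(
    barcode = corrected_bc,
    umi = parsed$umi[accepted_idx],
    read2 = r2[accepted_idx])

  stats <- c(n_total = n_total,
             n_exact = sum(exact),
             n_corrected = sum(!exact),
             n_ambiguous = sum(status == -1),
             n_no_match = sum(status == 0),
             n_malformed = sum(!ok))
  list(tags = tags, stats = stats)
}
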