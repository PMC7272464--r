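#' Hamming distance between equal-length sequences
#'
#' Vectorised position-wise mismatch count.  `a` and `b` are recycled to a
#' common length; paired strings must have equal width.  Any character
#' mismatch counts, so an `N` never matches anything but `N`.
#'
#' @param a,b character vectors of equal-length strings.
#' @return integer vector of mismatch counts.
#' @examples
#' hamming_distance("ACGTAC", "ACGTAT")
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  cpp_hamming(rep_len(as.character(a), n), rep_len(as.character(b), n))
}

# Derive a per-stage RNG seed from one global seed, salting with the stage
# name so stages can be rerun independently.  Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  salt <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + salt) %% 2147483647)
}

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_seq <- function(n, width) {
  if (n == 0) return(character(0))
  chars <- sample(c("A", "C", "G", "T"), n * width, replace = TRUE)
  do.call(paste0, asplit(matrix(chars, nrow = width), 1))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 0) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}
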