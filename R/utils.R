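#' Reverse complement of DNA sequences
#'
#' @param x character vector of sequences over A, C, G, T, N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  cpp_revcomp(toupper(as.character(x)))
}

#' Threshold-limited edit distance
#'
#' Bit-parallel (Myers) global edit distance between two sequences. When
#' `limit` is non-negative and the distance provably exceeds it, `NA` is
#' returned without completing the computation.
#'
#' @param a,b sequences (single strings).
#' @param limit non-negative cap on the distance, or a negative value to
#'   compute the distance exactly.
#' @return integer-valued distance, or `NA` if it exceeds `limit`.
#' @export
edit_distance <- function(a, b, limit = -1) {
  cpp_edit_distance(as.character(a), as.character(b), as.double(limit))
}

# internal: stop with a stage-prefixed message
stage_stop <- function(stage, msg, hint = NULL) {
  full <- sprintf("[%s] %s", stage, msg)
  if (!is.null(hint)) full <- paste0(full, "\n  hint: ", hint)
  stop(full, call. = FALSE)
}

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7L + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
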