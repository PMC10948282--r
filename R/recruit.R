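#' Build a canonical k-mer index
#'
#' Indexes the canonical form (lexicographic minimum of a k-mer and its
#' reverse complement) of every k-mer of the input sequences; windows
#' containing N are skipped.
#'
#' @param sequences data.frame of sequence records or character vector.
#' @param k odd k-mer size, 11 <= k <= 63.
#' @return a `kmer_index` with fields `k` and `members` (sorted).
#' @export
build_kmer_index <- function(sequences, k = 21) {
  k <- as.integer(k)
  if (k %% 2 == 0 || k < 11 || k > 63) stop("k must be odd and in [11, 63]")
  seqs <- if (is.data.frame(sequences)) sequences$seq else as.character(sequences)
  seqs <- toupper(seqs)
  res <- cpp_count_kmers(seqs, k)
  members <- res$kmer
  if (length(members) == 0) {
    warning("all sequences shorter than k: empty index")
  }
  structure(list(k = k, members = members), class = "kmer_index")
}

#' Recruit reads sharing k-mers with an index
#'
#' A read is recruited when the fraction of its canonical k-mers present in
#' the index is at least `min_fraction`. Reads shorter than k are never
#' recruited. Decisions are reported for every read; recruitment is
#' deterministic and order-independent.
#'
#' @param reads data.frame of sequence records.
#' @param index a [build_kmer_index()] result.
#' @param min_fraction recruitment threshold on the matched k-mer fraction.
#' @return list with `reads` (the recruited subset) and `decisions`
#'   (data.frame read_id, matched_fraction, recruited).
#' @export
recruit_reads <- function(reads, index, min_fraction = 0.2) {
  stopifnot(inherits(index, "kmer_index"))
  if (length(index$members) == 0) stop("empty k-mer index")
  frac <- cpp_match_fraction(reads$seq, index$members, index$k)
  rec <- frac >= min_fraction & nchar(reads$seq) >= index$k
  decisions <- data.frame(read_id = reads$id, matched_fraction = frac,
                          recruited = rec, stringsAsFactors = FALSE)
  list(reads = reads[rec, , drop = FALSE], decisions = decisions)
}
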