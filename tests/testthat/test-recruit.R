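test_that("k-mer index equals brute-force canonical enumeration", {
  set.seed(3)
  s <- rseq(200)
  idx <- build_kmer_index(s, k = 11)
  expect_setequal(idx$members, unique(brute_canon_kmers(s, 11)))

  one <- build_kmer_index(rseq(21), k = 21)
  expect_length(one$members, 1)

  s2 <- rseq(300)
  expect_identical(build_kmer_index(s2, 21)$members,
                   build_kmer_index(paste(revcomp(s2)), 21)$members)

  expect_error(build_kmer_index(s, k = 12), "odd")
  expect_warning(build_kmer_index(rseq(10), k = 21), "shorter than k")
})

test_that("recruitment separates locus reads from unrelated sequence", {
  set.seed(5)
  reference <- rseq(20000)
  idx <- build_kmer_index(reference, 21)
  reads <- data.frame(
    id = c("from_ref", "random", "tiny"),
    desc = "",
    seq = c(substr(reference, 2001, 7000), rseq(10000), rseq(10)),
    stringsAsFactors = FALSE)
  out <- recruit_reads(reads, idx, min_fraction = 0.2)
  dec <- out$decisions
  expect_equal(dec$matched_fraction[1], 1.0)
  expect_true(dec$recruited[1])
  expect_lt(dec$matched_fraction[2], 0.01)
  expect_false(dec$recruited[2])
  expect_false(dec$recruited[3]) # shorter than k is never recruited
})

test_that("a too-divergent reference recruits poorly", {
  set.seed(6)
  reference <- rseq(5000)
  divergent <- mutate_subs(reference, round(0.15 * 5000))
  idx <- build_kmer_index(reference, 21)
  starts <- seq(1, 4000, by = 100)
  reads <- data.frame(id = sprintf("d%03d", seq_along(starts)), desc = "",
                      seq = vapply(starts, function(s)
                        substr(divergent, s, s + 999), character(1)),
                      stringsAsFactors = FALSE)
  out <- recruit_reads(reads, idx, min_fraction = 0.1)
  expect_lt(mean(out$decisions$recruited), 0.5)
})

test_that("recruitment is monotone in min_fraction", {
  set.seed(8)
  reference <- rseq(5000)
  idx <- build_kmer_index(reference, 21)
  reads <- data.frame(
    id = sprintf("m%02d", 1:20), desc = "",
    seq = vapply(1:20, function(i) {
      base <- substr(reference, 100 * i, 100 * i + 800)
      mutate_subs(base, sample(0:60, 1))
    }, character(1)),
    stringsAsFactors = FALSE)
  loose <- recruit_reads(reads, idx, min_fraction = 0.05)
  tight <- recruit_reads(reads, idx, min_fraction = 0.4)
  expect_true(all(tight$reads$id %in% loose$reads$id))
  # decisions are reported for every read and deterministic
  expect_equal(nrow(loose$decisions), nrow(reads))
  expect_identical(recruit_reads(reads, idx, 0.05)$decisions, loose$decisions)
})
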