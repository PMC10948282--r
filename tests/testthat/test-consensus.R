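test_that("medoid minimizes total distance", {
  seqs <- rep("ACGTACGTAC", 3)
  D <- matrix(0, 3, 3)
  expect_equal(medoid(1:3, seqs, D), 1)

  seqs2 <- c("AAAAAAAAAA", "AAAAAAAAAA", "CCCCCCCCCC")
  D2 <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10, 0), 3)
  expect_equal(medoid(1:3, seqs2, D2), 1)

  set.seed(40)
  for (trial in 1:15) {
    n <- sample(4:10, 1)
    base <- rseq(150)
    seqs <- vapply(1:n, function(i) mutate_subs(base, sample(0:8, 1)),
                   character(1))
    D <- matrix(NA_real_, n, n); diag(D) <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- dp_ed(seqs[i], seqs[j])
    }
    tot <- rowSums(D)
    expect_equal(medoid(1:n, seqs, D), which.min(tot))
  }
  # exceeds-limit entries are computed on demand
  Dna <- matrix(NA_real_, 3, 3); diag(Dna) <- 0
  s3 <- c("ACACACACAC", "ACACACACAC", "GTGTGTGTGT")
  expect_equal(medoid(1:3, s3, Dna), 1)
})

test_that("polishing is a fixed point on clean input and corrects noise", {
  truth <- local({ set.seed(41); rseq(500) })
  expect_identical(polish(truth, rep(truth, 5)), truth)
  # polishing any seed against identical loops returns the loops' sequence
  seed0 <- mutate_subs(truth, 12)
  expect_identical(polish(seed0, rep(truth, 7)), truth)

  set.seed(42)
  hits <- 0
  for (trial in 1:20) {
    loops <- vapply(1:20, function(i)
      ribomorph:::cpp_inject_errors(truth, 0.02, 0.015, 0.015, 1.5),
      character(1))
    cons <- polish(loops[1], loops)
    if (edit_distance(truth, cons) <= 0.001 * nchar(truth)) hits <- hits + 1
  }
  expect_gte(hits, 19) # >= 95% of seeded trials recover the truth
})

test_that("the genome-wide consensus walk is greedy by edge coverage", {
  fx <- single_morph_fixture()
  cons <- genome_wide_consensus(fx$graph, fx$anchor, 2000)
  expect_equal(match_morphs(fx$morph, cons)$identity, 1.0)
})

test_that("paired SNP bubbles yield a mosaic consensus matching no morph", {
  set.seed(43)
  # two morphs differing at two well-separated SNP bubbles with equal copy
  # numbers; the walk decides each bubble independently by its deterministic
  # tie-break, and with these alleles it pairs A's first allele with B's
  # second: a mosaic that exists in neither morph
  base <- rseq(3000)
  v <- strsplit(base, "", fixed = TRUE)[[1]]
  vA <- v; vA[1000] <- "A"; vA[2000] <- "T"
  vB <- v; vB[1000] <- "C"; vB[2000] <- "G"
  morphA <- paste(vA, collapse = ""); morphB <- paste(vB, collapse = "")
  arrA <- strrep(morphA, 6); arrB <- strrep(morphB, 6)
  reads <- rbind(tiling_reads(arrA, 5000, 450), tiling_reads(arrB, 5000, 450))
  reads$id <- sprintf("r%03d", seq_len(nrow(reads)))
  g <- clean_graph(build_allele_graph(reads, k = 31, solid_min = 2),
                   min_node_coverage = 2)
  anchor <- select_anchor_node(g)
  cons <- genome_wide_consensus(g, anchor, 3000)
  mA <- match_morphs(morphA, cons)
  mB <- match_morphs(morphB, cons)
  # each individual allele is genomic (the consensus still matches both
  # morphs at >99.9%), yet the combination matches neither exactly
  expect_lt(mA$identity, 1)
  expect_lt(mB$identity, 1)
  expect_gt(mA$identity, 0.999)
  expect_gt(mB$identity, 0.999)
})
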