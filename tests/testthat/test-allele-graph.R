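test_that("homopolymer compression examples and roundtrip", {
  r <- hpc_compress("AAACCG")
  expect_equal(r$compressed, "ACG")
  expect_equal(r$runs, c(3L, 2L, 1L))
  expect_equal(hpc_expand(r), "AAACCG")

  r2 <- hpc_compress("ACGT")
  expect_equal(r2$compressed, "ACGT")
  expect_equal(r2$runs, rep(1L, 4))

  set.seed(10)
  for (i in 1:25) {
    s <- paste(rep(sample(c("A", "C", "G", "T"), 60, TRUE),
                   sample(1:4, 60, TRUE)), collapse = "")
    expect_equal(hpc_expand(hpc_compress(s)), s)
  }
  expect_warning(hpc_compress("AANNTT"), "N runs dropped")
})

test_that("a single error-free template collapses to one unitig", {
  set.seed(12)
  tmpl <- rseq(2000)
  reads <- data.frame(id = sprintf("c%02d", 1:10), desc = "",
                      seq = rep(tmpl, 10), stringsAsFactors = FALSE)
  g <- build_allele_graph(reads, k = 31, solid_min = 2)
  expect_equal(nrow(g$nodes), 1)
  exp1 <- expand_node(g, 1)
  hp <- hpc_expand(hpc_compress(tmpl))
  expect_true(exp1 == hp || exp1 == paste(revcomp(hp)))
})

test_that("one SNP with long shared flanks makes a four-unitig bubble", {
  set.seed(13)
  a <- rseq(1200)
  v <- strsplit(a, "", fixed = TRUE)[[1]]
  v[600] <- setdiff(c("A", "C", "G", "T"), v[600])[1]
  b <- paste(v, collapse = "")
  reads <- data.frame(id = sprintf("t%02d", 1:20), desc = "",
                      seq = c(rep(a, 10), rep(b, 10)), stringsAsFactors = FALSE)
  g <- build_allele_graph(reads, k = 31, solid_min = 2)
  expect_equal(nrow(g$nodes), 4)
  expect_equal(nrow(g$edges), 4)
})

test_that("solid k-mers partition exactly onto unitigs", {
  set.seed(14)
  reads <- data.frame(id = sprintf("k%02d", 1:12), desc = "",
                      seq = replicate(12, mutate_subs(rseq(1500), 8)),
                      stringsAsFactors = FALSE)
  # make half the reads copies so some k-mers are solid
  reads$seq[7:12] <- reads$seq[1:6]
  g <- build_allele_graph(reads, k = 31, solid_min = 2)
  comp <- vapply(reads$seq, function(s) hpc_compress(s)$compressed,
                 character(1), USE.NAMES = FALSE)
  counts <- table(brute_canon_kmers(comp, 31))
  solid <- names(counts)[counts >= 2]
  from_unitigs <- brute_canon_kmers(g$nodes$seq, 31)
  expect_equal(sort(from_unitigs), sort(solid)) # once and exactly once
})

test_that("graph construction is read-order independent", {
  fx <- single_morph_fixture()
  set.seed(15)
  g2 <- clean_graph(build_allele_graph(fx$reads[sample(nrow(fx$reads)), ],
                                       k = 31, solid_min = 2),
                    min_node_coverage = 2)
  expect_equal(g2$nodes$seq, fx$graph$nodes$seq)
  expect_equal(g2$edges, fx$graph$edges)
})

test_that("cleaning removes low-coverage junk and keeps the cycle", {
  set.seed(16)
  fx <- single_morph_fixture()
  junk_tail <- rseq(600)
  junk <- paste0(substr(fx$array, 1, 600), junk_tail)
  reads2 <- rbind(fx$reads,
                  data.frame(id = c("j1", "j2", "j3"), desc = "",
                             seq = rep(junk, 3), stringsAsFactors = FALSE))
  g_dirty <- build_allele_graph(reads2, k = 31, solid_min = 2)
  expect_gt(nrow(g_dirty$nodes), 1)
  g_clean <- clean_graph(g_dirty, min_node_coverage = 4)
  expect_gte(min(g_clean$nodes$cov), 4)
  expect_equal(nrow(g_clean$nodes), 1) # back to the single-morph cycle
  # cleaning an already-clean graph is a no-op
  again <- clean_graph(fx$graph, min_node_coverage = 2)
  expect_equal(again$nodes$seq, fx$graph$nodes$seq)
})

test_that("error-free tandem array yields a cycle expanding to the morph", {
  fx <- single_morph_fixture()
  expect_equal(nrow(fx$graph$nodes), 1)
  cons <- genome_wide_consensus(fx$graph, fx$anchor, 2000)
  mm <- match_morphs(fx$morph, cons)
  expect_equal(mm$identity, 1.0)
  expect_true(mm$is_match)
})
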