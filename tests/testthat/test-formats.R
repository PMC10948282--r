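test_that("FASTA parsing concatenates wrapped lines and cleans bases", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a desc", "AC", "GT"), f)
  recs <- read_sequences(f)
  expect_equal(recs$id, "a")
  expect_equal(recs$desc, "desc")
  expect_equal(recs$seq, "ACGT")

  writeLines(c(">x", "acgu"), f)
  expect_equal(read_sequences(f)$seq, "ACGT") # lowercase and U -> T

  writeLines(character(0), f)
  expect_equal(nrow(read_sequences(f)), 0)    # empty file, no error
})

test_that("FASTQ parsing decodes Phred+33 qualities", {
  f <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r", "ACGT", "+", "IIII"), f)
  recs <- read_sequences(f)
  expect_equal(recs$seq, "ACGT")
  expect_equal(recs$qual[[1]], rep(40L, 4))
})

test_that("malformed records raise parse errors naming the line", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACXT"), f)
  expect_error(read_sequences(f), "invalid base.*line 1")
  writeLines(c("@r", "ACGT", "+", "III"), f)
  expect_error(read_sequences(f), "length.*line 4")
  writeLines(c("> ", "ACGT"), f)
  expect_error(read_sequences(f), "empty sequence id")
  writeLines(c("ACGT", ">a", "ACGT"), f)
  expect_error(read_sequences(f, format = "fasta"), "before first header")
  writeLines(c(">a", "AC", ">a", "GT"), f)
  expect_error(read_sequences(f), "duplicate")
})

test_that("FASTA/FASTQ roundtrips are identity and writers deterministic", {
  set.seed(7)
  n <- 20
  recs <- data.frame(id = sprintf("s%02d", sample(n)), desc = "x y",
                     seq = vapply(1:n, function(i) rseq(sample(10:300, 1)),
                                  character(1)),
                     stringsAsFactors = FALSE)
  recs$qual <- lapply(nchar(recs$seq), function(l) sample(0:60, l, TRUE))
  fa <- withr::local_tempfile(fileext = ".fa")
  fq <- withr::local_tempfile(fileext = ".fq")
  write_fasta(recs, fa)
  back <- read_sequences(fa)
  ord <- order(recs$id)
  expect_equal(back$id, recs$id[ord])
  expect_equal(back$seq, recs$seq[ord])
  write_fastq(recs, fq)
  back2 <- read_sequences(fq)
  expect_equal(back2$seq, recs$seq[ord])
  expect_equal(back2$qual, recs$qual[ord])
  # determinism: shuffled input writes byte-identical output
  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs[sample(n), ], fa2)
  expect_equal(unname(tools::md5sum(fa)), unname(tools::md5sum(fa2)))
})

test_that("reader agrees with Biostrings on random FASTA", {
  set.seed(11)
  recs <- data.frame(id = sprintf("q%02d", 1:10), desc = "",
                     seq = vapply(1:10, function(i) rseq(sample(50:500, 1)),
                                  character(1)),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  ours <- read_sequences(f)
  bs <- Biostrings::readDNAStringSet(f)
  expect_equal(ours$seq, unname(as.character(bs)))
  expect_equal(ours$id, names(bs))
})

test_that("GFA roundtrip reproduces nodes, edges and coverages", {
  fx <- single_morph_fixture()
  f <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(fx$graph, f)
  g2 <- read_gfa(f)
  expect_equal(g2$k, fx$graph$k)
  expect_equal(nrow(g2$nodes), nrow(fx$graph$nodes))
  for (i in seq_len(nrow(fx$graph$nodes))) {
    expect_equal(expand_node(g2, g2$nodes$id[i]),
                 expand_node(fx$graph, fx$graph$nodes$id[i]))
  }
  expect_equal(g2$nodes$cov, fx$graph$nodes$cov, tolerance = 1e-6)
  expect_equal(g2$edges[, c("from", "from_o", "to", "to_o")],
               fx$graph$edges[, c("from", "from_o", "to", "to_o")])

  # header-only file -> empty graph; L line to missing node -> error
  writeLines("H\tVN:Z:1.0\tkc:i:31", f)
  expect_equal(nrow(read_gfa(f)$nodes), 0)
  writeLines(c("H\tVN:Z:1.0\tkc:i:31", "S\t1\tACGT\tdp:f:1",
               "L\t1\t+\t9\t+\t30M"), f)
  expect_error(read_gfa(f), "absent segment")
})
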