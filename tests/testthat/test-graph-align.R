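test_that("anchors equal brute-force k-mer intersection", {
  fx <- single_morph_fixture()
  al <- fx$aligner
  set.seed(20)
  read <- substr(fx$array, 301, 900)
  got <- anchor_read(read, al)
  # brute force: every shared 17-mer in both orientations
  node_seq <- al$node_exp[fx$graph$nodes$id[1]]
  expected <- list()
  for (i in seq_len(nchar(read) - 16)) {
    w <- substr(read, i, i + 16)
    hits_f <- gregexpr(w, node_seq, fixed = TRUE)[[1]]
    if (hits_f[1] != -1) for (h in hits_f) {
      expected[[length(expected) + 1]] <- c(i - 1L, h - 1L, 1L)
    }
    hits_r <- gregexpr(paste(revcomp(w)), node_seq, fixed = TRUE)[[1]]
    if (hits_r[1] != -1) for (h in hits_r) {
      expected[[length(expected) + 1]] <- c(i - 1L, h - 1L, -1L)
    }
  }
  exp_df <- do.call(rbind, expected)
  got_key <- paste(got$read_pos, got$node_pos, got$orient)
  exp_key <- paste(exp_df[, 1], exp_df[, 2], exp_df[, 3])
  expect_setequal(got_key, exp_key)

  # read with no shared k-mers anchors nowhere
  set.seed(21)
  expect_equal(nrow(anchor_read(rseq(500), al)), 0)
})

test_that("error-free reads recover the exact walk at identity 1", {
  fx <- single_morph_fixture()
  read <- substr(fx$array, 501, 6500)
  aps <- align_read(read, fx$aligner, read_id = "w")
  expect_length(aps, 1)
  expect_equal(aps[[1]]$identity, 1.0)
  expect_true(ribomorph:::validate_alignment_path(fx$aligner, aps[[1]]))
  loops <- extract_loops(aps[[1]], fx$anchor, 2000, fx$aligner)
  expect_gte(length(loops), 2) # a 3-unit read spans >= 2 full traversals
  for (l in loops) {
    expect_equal(match_morphs(fx$morph, l$sequence)$identity, 1.0)
  }
})

test_that("noisy reads still align with high identity; random reads do not", {
  fx <- single_morph_fixture()
  set.seed(22)
  tmpl <- substr(fx$array, 1001, 7000)
  noisy <- ribomorph:::cpp_inject_errors(tmpl, 0.025, 0.012, 0.013, 1.5)
  aps <- align_read(noisy, fx$aligner, read_id = "n")
  expect_gte(length(aps), 1)
  expect_gte(aps[[1]]$identity, 0.9)
  for (ap in aps) {
    expect_true(ribomorph:::validate_alignment_path(fx$aligner, ap))
  }
  expect_length(align_read(rseq(5000), fx$aligner), 0)
})

test_that("aligning the reverse complement mirrors the path", {
  fx <- single_morph_fixture()
  set.seed(23)
  noisy <- ribomorph:::cpp_inject_errors(substr(fx$array, 2001, 8000),
                                         0.025, 0.012, 0.013, 1.5)
  fwd <- align_read(noisy, fx$aligner, read_id = "f")
  rev <- align_read(paste(revcomp(noisy)), fx$aligner, read_id = "r")
  expect_equal(length(fwd), length(rev))
  expect_equal(fwd[[1]]$identity, rev[[1]]$identity, tolerance = 1e-9)
  flipped <- data.frame(id = rev(rev[[1]]$path$id),
                        o = ifelse(rev(rev[[1]]$path$o) == "+", "-", "+"),
                        stringsAsFactors = FALSE)
  expect_equal(fwd[[1]]$path, flipped)
})
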