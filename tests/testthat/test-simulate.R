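test_that("source panel hits the divergence target and is reproducible", {
  p0 <- sim_params(n_sources = 3, morph_length = 1000, mosaic_divergence = 0,
                   seed = 5)
  panel0 <- generate_source_panel(p0)
  expect_true(all(panel0 == panel0[1])) # zero target: identical sources

  p <- sim_params(n_sources = 2, morph_length = 1000, mosaic_divergence = 0.05,
                  seed = 5)
  panel <- generate_source_panel(p)
  d <- dp_ed(panel[1], panel[2]) / mean(nchar(panel))
  expect_gte(d, 0.04)
  expect_lte(d, 0.06)

  expect_identical(generate_source_panel(p), panel) # same seed, same panel
  expect_error(generate_source_panel(sim_params(mosaic_divergence = 0.35)),
               "unreachable divergence")
})

test_that("mosaic segments match their named sources before mutation", {
  p <- sim_params(n_sources = 4, morph_length = 2000, n_morphs = 3,
                  mosaic_divergence = 0.042, mutation_rate = 0.002, seed = 9)
  panel <- generate_source_panel(p)
  morphs <- generate_morphs(panel, p)
  for (m in morphs) {
    mosaic <- attr(m, "mosaic")
    segs <- attr(m, "mosaic_segments")
    for (i in seq_len(nrow(segs))) {
      piece <- substr(mosaic, segs$start[i] + 1, segs$end[i])
      if (nchar(piece) < 20) next
      expect_true(grepl(piece, panel[segs$source[i]], fixed = TRUE),
                  label = sprintf("segment %d of %s in source %d",
                                  i, m$morph_id, segs$source[i]))
    }
    # mutated segments still tile the final sequence
    expect_equal(m$source_segments$start[1], 0)
    expect_equal(m$source_segments$end[nrow(m$source_segments)],
                 nchar(m$sequence))
    expect_true(m$copy_count >= 1)
  }
})

test_that("random mutation count is binomially plausible", {
  p <- sim_params(n_sources = 2, morph_length = 20000, n_morphs = 4,
                  mosaic_divergence = 0.01, mutation_rate = 0.002, seed = 21)
  panel <- generate_source_panel(p)
  morphs <- generate_morphs(panel, p)
  expected <- 0.002 * 20000
  sigma <- sqrt(20000 * 0.002 * 0.998)
  for (m in morphs) {
    observed <- edit_distance(attr(m, "mosaic"), m$sequence)
    expect_lte(abs(observed - expected), 3 * sigma + 3)
  }
})

test_that("arrays conserve copy counts and length", {
  morphs <- list(list(morph_id = "a", sequence = rseq(500), copy_count = 2L),
                 list(morph_id = "b", sequence = rseq(700), copy_count = 3L))
  arr <- build_array(morphs, seed = 3)
  expect_equal(nchar(arr$array_sequence), 2 * 500 + 3 * 700)
  tab <- table(arr$unit_order)
  expect_equal(as.integer(tab[c("a", "b")]), c(2L, 3L))
  one <- build_array(list(list(morph_id = "a", sequence = morphs[[1]]$sequence,
                               copy_count = 1L)), seed = 1)
  expect_equal(one$array_sequence, morphs[[1]]$sequence)
})

test_that("simulated reads respect origins, coverage and error rates", {
  set.seed(2)
  target <- rseq(60000)
  arr <- list(array_sequence = target)
  prof0 <- read_profile(mean_length = 6000, sigma = 0.2, sub_rate = 0,
                        ins_rate = 0, del_rate = 0)
  reads <- simulate_reads(arr, prof0, coverage = 5, seed = 11)
  total <- sum(nchar(reads$seq))
  expect_gte(total, 5 * 60000)
  expect_lte(total, 1.06 * 5 * 60000)
  # error-free reads equal their recorded origin interval
  for (i in seq_len(min(nrow(reads), 15))) {
    m <- regmatches(reads$desc[i],
                    regexec("origin=(\\d+)-(\\d+) strand=([+-])", reads$desc[i]))[[1]]
    s <- as.integer(m[2]); e <- as.integer(m[3])
    tmpl <- substr(target, s + 1, e)
    obs <- if (m[4] == "-") paste(revcomp(reads$seq[i])) else reads$seq[i]
    expect_equal(obs, tmpl)
  }
  expect_identical(simulate_reads(arr, prof0, coverage = 5, seed = 11), reads)

  # substitution-only profile: observed divergence close to the rate
  prof5 <- read_profile(mean_length = 6000, sigma = 0.2, sub_rate = 0.05,
                        ins_rate = 0, del_rate = 0)
  r5 <- simulate_reads(arr, prof5, coverage = 1, seed = 4)
  i <- which.max(nchar(r5$seq))
  m <- regmatches(r5$desc[i],
                  regexec("origin=(\\d+)-(\\d+) strand=([+-])", r5$desc[i]))[[1]]
  tmpl <- substr(target, as.integer(m[2]) + 1, as.integer(m[3]))
  obs <- if (m[4] == "-") paste(revcomp(r5$seq[i])) else r5$seq[i]
  div <- edit_distance(obs, tmpl) / nchar(tmpl)
  sigma <- 3 * sqrt(0.05 * 0.95 / nchar(tmpl))
  expect_lte(abs(div - 0.05), sigma + 0.005)

  expect_warning(simulate_reads(list(array_sequence = rseq(1000)),
                                prof0, coverage = 1, seed = 1),
                 "truncated")
})
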