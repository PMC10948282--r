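test_that("morph matching is rotation-aware and thresholded at 99/99", {
  set.seed(50)
  a <- rseq(6000)
  expect_true(match_morphs(a, a)$is_match)
  expect_equal(match_morphs(a, a)$identity, 1.0)

  rot <- paste0(substr(a, 1001, 6000), substr(a, 1, 1000))
  mrot <- match_morphs(a, rot)
  expect_equal(mrot$identity, 1.0)
  expect_true(mrot$is_match)

  rc <- paste(revcomp(rot))
  expect_true(match_morphs(a, rc)$is_match) # opposite strand still matches

  big <- rseq(45000)
  near <- mutate_subs(big, 200)  # ~0.45% divergence: match
  far <- mutate_subs(big, 600)   # ~1.3% divergence: no match
  expect_true(match_morphs(big, near)$is_match)
  expect_false(match_morphs(big, far)$is_match)
})

test_that("match decision is symmetric on random pairs", {
  set.seed(51)
  for (trial in 1:10) {
    a <- rseq(1500)
    b <- mutate_subs(a, sample(c(3, 10, 16, 40), 1))
    expect_equal(match_morphs(a, b)$is_match, match_morphs(b, a)$is_match)
  }
})

test_that("error classification separates homopolymer and microsatellite indels", {
  hp <- match_morphs("AAAA", "AAA", trace = TRUE)
  f <- classify_errors(hp)
  expect_equal(unname(f["homopolymer_indel"]), 1)

  ms <- match_morphs("ACACAC", "ACAC", trace = TRUE)
  f2 <- classify_errors(ms)
  expect_equal(unname(f2["microsatellite_indel"]), 1)

  sub <- match_morphs("ACGTACGTAA", "ACGTGCGTAA", trace = TRUE)
  f3 <- classify_errors(sub)
  expect_equal(unname(f3["other"]), 1)

  set.seed(52)
  for (trial in 1:5) {
    a <- rseq(400)
    b <- mutate_subs(a, 6)
    fr <- classify_errors(match_morphs(a, b, trace = TRUE))
    expect_equal(sum(fr), 1, tolerance = 1e-9)
  }
})

test_that("assembly scoring reproduces the hand-computed correlation", {
  set.seed(53)
  seqs <- vapply(1:3, function(i) rseq(800), character(1))
  truth <- lapply(1:3, function(i)
    list(morph_id = paste0("t", i), sequence = seqs[i], copy_count = i))
  pred <- lapply(1:3, function(i)
    list(morph_id = paste0("p", i), sequence = seqs[i],
         coverage = c(3, 5, 9)[i]))
  ev <- score_assembly(truth, pred)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)
  expect_equal(ev$pearson_r, 0.982, tolerance = 1e-3)
  expect_equal(ev$mean_mismatches, 0)

  # empty predictions: zero sensitivity, specificity reported absent
  ev0 <- score_assembly(truth, list())
  expect_equal(ev0$sensitivity, 0)
  expect_true(is.na(ev0$specificity))
})

test_that("assembly scoring is permutation-invariant", {
  set.seed(54)
  seqs <- vapply(1:4, function(i) rseq(600), character(1))
  truth <- lapply(1:4, function(i)
    list(morph_id = paste0("t", i), sequence = seqs[i], copy_count = i))
  pred <- lapply(1:3, function(i)
    list(morph_id = paste0("p", i), sequence = mutate_subs(seqs[i], 1),
         coverage = 10 * i))
  e1 <- score_assembly(truth, pred)
  e2 <- score_assembly(truth[c(3, 1, 4, 2)], pred[c(2, 3, 1)])
  expect_equal(e1$sensitivity, e2$sensitivity)
  expect_equal(e1$specificity, e2$specificity)
  expect_equal(e1$pearson_r, e2$pearson_r)
})

test_that("abundance filters follow the copy/coverage rule", {
  set.seed(55)
  s <- vapply(1:3, function(i) rseq(500), character(1))
  truth <- list(list(morph_id = "t1", sequence = s[1], copy_count = 8),
                list(morph_id = "t2", sequence = s[2], copy_count = 1),
                list(morph_id = "t3", sequence = s[3], copy_count = 1))
  pred <- list(list(morph_id = "p1", sequence = s[1], coverage = 50),
               list(morph_id = "p2", sequence = s[2], coverage = 40))
  ev <- score_assembly(truth, pred, min_truth_copies = 5,
                       min_pred_coverage = 30)
  # t1 (copies 8) and t2 (matched by coverage-40 prediction) qualify; the
  # unmatched single-copy t3 does not
  expect_equal(ev$n_truth_qualified, 2L)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)
})
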