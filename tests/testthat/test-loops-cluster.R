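fake_graph <- function(covs, lens) {
  n <- length(covs)
  structure(list(k = 31L,
                 nodes = data.frame(id = seq_len(n), seq = strrep("ACGT", 10),
                                    cov = covs, len = lens,
                                    stringsAsFactors = FALSE),
                 runs = replicate(n, rep(1L, 40), simplify = FALSE),
                 edges = data.frame(from = integer(), from_o = character(),
                                    to = integer(), to_o = character(),
                                    cov = numeric())),
            class = "allele_graph")
}

test_that("anchor node selection maximizes coverage x length", {
  expect_equal(select_anchor_node(fake_graph(10, 100)), 1)
  expect_equal(select_anchor_node(fake_graph(c(10, 50), c(100, 100))), 2)
  set.seed(30)
  for (i in 1:20) {
    covs <- runif(12, 10, 60) # within a 3x band: no repeat exclusion
    lens <- sample(50:500, 12)
    g <- fake_graph(covs, lens)
    expect_equal(select_anchor_node(g), which.max(covs * lens))
  }
})

test_that("loop extraction counts match string-search expectations", {
  fx <- single_morph_fixture()
  # a read shorter than one unit visits the anchor at most once: no loops
  short <- substr(fx$array, 3001, 4200)
  aps <- align_read(short, fx$aligner, read_id = "s")
  if (length(aps)) {
    expect_length(extract_loops(aps[[1]], fx$anchor, 2000, fx$aligner), 0)
  }
  # error-free full-length read: loops = covered anchor starts - 1;
  # anchor starts are located by an anchor-prefix string search
  anchor_seq <- expand_node(fx$graph, fx$anchor)
  prefix <- substr(anchor_seq, 1, 60)
  long <- substr(fx$array, 1, 12000)
  hits <- gregexpr(prefix, long, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    prefix <- paste(revcomp(substr(anchor_seq, nchar(anchor_seq) - 59,
                                   nchar(anchor_seq))))
    hits <- gregexpr(prefix, long, fixed = TRUE)[[1]]
  }
  occ <- sum(hits + 60 - 1 <= nchar(long))
  aps <- align_read(long, fx$aligner, read_id = "l")
  loops <- extract_loops(aps[[1]], fx$anchor, 2000, fx$aligner)
  expect_equal(length(loops), occ - 1)
})

test_that("pairwise distances match full DP on pairs within the limit", {
  expect_equal(pairwise_distances(c("ACGT", "ACGT"), 10)[1, 2], 0)
  expect_equal(pairwise_distances(c("ACGT", "ACT"), 10)[1, 2], 1)
  set.seed(31)
  for (trial in 1:10) {
    base <- rseq(250)
    seqs <- c(base, vapply(1:9, function(i)
      mutate_subs(base, sample(0:5, 1)), character(1)))
    D <- pairwise_distances(seqs, limit = 30)
    for (i in 1:9) for (j in (i + 1):10) {
      expect_equal(D[i, j], dp_ed(seqs[i], seqs[j]),
                   label = sprintf("trial %d pair %d-%d", trial, i, j))
    }
  }
  # pairs beyond the limit are flagged, not mis-reported
  far <- c(rseq(300), rseq(300))
  expect_true(is.na(pairwise_distances(far, 20)[1, 2]))
})

test_that("rough clusters equal connected components", {
  D <- matrix(NA_real_, 3, 3); diag(D) <- 0
  expect_length(rough_cluster(D, 10), 3) # all exceed: singletons

  D2 <- matrix(NA_real_, 3, 3); diag(D2) <- 0
  D2[1, 2] <- D2[2, 1] <- 5
  D2[2, 3] <- D2[3, 2] <- 5
  D2[1, 3] <- D2[3, 1] <- 30
  expect_equal(rough_cluster(D2, 10), list(1:3)) # transitive join

  set.seed(32)
  for (trial in 1:25) {
    n <- sample(5:25, 1)
    D <- matrix(NA_real_, n, n); diag(D) <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.2) D[i, j] <- D[j, i] <- sample(0:30, 1)
    }
    thr <- sample(5:20, 1)
    ours <- rough_cluster(D, thr)
    adj <- !is.na(D) & D <= thr
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                              diag = FALSE)
    comp <- igraph::components(gr)$membership
    oracle <- unname(split(seq_len(n), comp))
    key <- function(cl) sort(vapply(cl, function(x) paste(sort(x), collapse = ","),
                                    character(1)))
    expect_equal(key(ours), key(oracle))
  }
})

test_that("epsilon estimation follows the within-rough-cluster mean", {
  D <- matrix(0, 4, 4)
  expect_equal(estimate_epsilon(list(1:4), D, min_epsilon = 1), 1)

  D2 <- matrix(NA_real_, 3, 3); diag(D2) <- 0
  D2[1, 2] <- D2[2, 1] <- 10
  D2[1, 3] <- D2[3, 1] <- 20
  D2[2, 3] <- D2[3, 2] <- 30
  expect_equal(estimate_epsilon(list(1:3), D2, min_epsilon = 1), 20)

  # pooling divergent loop families never shrinks epsilon
  set.seed(33)
  for (trial in 1:50) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    w1 <- matrix(sample(0:10, n1^2, TRUE), n1); w1 <- pmax(w1, t(w1)); diag(w1) <- 0
    w2 <- matrix(sample(0:10, n2^2, TRUE), n2); w2 <- pmax(w2, t(w2)); diag(w2) <- 0
    between <- matrix(sample(60:120, n1 * n2, TRUE), n1, n2)
    D <- rbind(cbind(w1, between), cbind(t(between), w2))
    e1 <- estimate_epsilon(list(seq_len(n1)), w1, 1)
    e2 <- estimate_epsilon(list(seq_len(n2)), w2, 1)
    pooled <- estimate_epsilon(list(seq_len(n1 + n2)), D, 1)
    expect_gte(pooled, min(e1, e2))
  }
})

test_that("DBSCAN matches the reference implementation on random instances", {
  expect_equal(length(dbscan_cluster(1:6, matrix(0, 6, 6), 5, 5)$clusters), 1)
  two <- matrix(500, 20, 20)
  two[1:10, 1:10] <- 0; two[11:20, 11:20] <- 0
  res <- dbscan_cluster(1:20, two, 5, 5)
  expect_length(res$clusters, 2)
  expect_length(res$noise, 0)

  set.seed(34)
  instances <- lapply(1:200, function(t) {
    n <- sample(6:20, 1)
    pts <- matrix(sample(0:40, 2 * n, TRUE), ncol = 2)
    D <- as.matrix(stats::dist(pts, method = "manhattan"))
    dimnames(D) <- NULL
    list(D = D, eps = sample(3:12, 1), min_pts = sample(2:5, 1))
  })
  oracle <- sklearn_dbscan_batch(instances)
  for (t in seq_along(instances)) {
    it <- instances[[t]]
    ours <- dbscan_cluster(seq_len(nrow(it$D)), it$D, it$eps, it$min_pts)
    labs <- unlist(oracle[[t]]$labels)
    core_oracle <- as.integer(unlist(oracle[[t]]$core))
    if (length(core_oracle) == 0) core_oracle <- integer(0)
    # identical core-point partition
    adj <- it$D <= it$eps
    ours_core <- which(rowSums(adj) >= it$min_pts)
    expect_true(setequal(ours_core, core_oracle),
                label = sprintf("instance %d core set", t))
    ours_assign <- rep(0L, nrow(it$D))
    for (ci in seq_along(ours$clusters)) ours_assign[ours$clusters[[ci]]] <- ci
    # noise sets agree
    expect_setequal(ours$noise, which(labs == -1))
    # core points cluster identically (up to label renaming)
    if (length(core_oracle)) {
      tab <- table(ours_assign[core_oracle], labs[core_oracle])
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1),
                  label = sprintf("instance %d core partition", t))
    }
    # border points land in a cluster containing a core within eps
    border <- setdiff(which(labs != -1), core_oracle)
    for (b in border) {
      cl <- ours$clusters[[ours_assign[b]]]
      expect_true(any(it$D[b, intersect(cl, ours_core)] <= it$eps))
    }
  }
})

test_that("higher epsilon clusters are coarser and totals are conserved", {
  set.seed(35)
  n <- 30
  pts <- matrix(sample(0:50, 2 * n, TRUE), ncol = 2)
  D <- as.matrix(stats::dist(pts, method = "manhattan"))
  dimnames(D) <- NULL
  r1 <- dbscan_cluster(1:n, D, 4, 3)
  r2 <- dbscan_cluster(1:n, D, 12, 3)
  # conservation
  expect_equal(sum(lengths(r1$clusters)) + length(r1$noise), n)
  expect_equal(sum(lengths(r2$clusters)) + length(r2$noise), n)
  # nesting: the core points of every fine cluster end up in a single
  # coarse cluster (border assignment may tie-break differently)
  fine_core <- which(rowSums(D <= 4) >= 3)
  assign2 <- rep(0L, n)
  for (ci in seq_along(r2$clusters)) assign2[r2$clusters[[ci]]] <- ci
  for (cl in r1$clusters) {
    hosts <- unique(assign2[intersect(cl, fine_core)])
    hosts <- hosts[hosts != 0]
    expect_lte(length(hosts), 1)
  }
})
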