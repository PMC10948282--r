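#' Select the loop anchor node
#'
#' The loop boundary is fixed at the node maximizing coverage times expanded
#' length (ties broken by the smaller id) — a high-confidence, long stretch
#' that nearly every repeat copy traverses exactly once. Collapsed tandem
#' repeat nodes (coverage far above the single-copy ceiling; see
#' `collapsed_repeat_nodes`) are excluded as anchors.
#'
#' @param graph an `allele_graph`.
#' @return node id.
#' @export
select_anchor_node <- function(graph) {
  nd <- graph$nodes
  if (nrow(nd) == 0) stop("empty graph")
  cand <- nd[!collapsed_repeat_nodes(nd), , drop = FALSE]
  if (nrow(cand) == 0) cand <- nd
  sc <- cand$cov * cand$len
  cand$id[order(-sc, cand$id)][1]
}

# nodes whose coverage stands far above the single-copy ceiling (weighted
# 95th percentile of node coverage) are collapsed tandem repeats traversed
# several times per repeat copy
collapsed_repeat_nodes <- function(nodes) {
  ceiling95 <- weighted_quantile(nodes$cov, nodes$len, 0.95)
  nodes$cov > 3 * ceiling95
}

weighted_quantile <- function(x, w, q) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= q)[1]]
}

weighted_median <- function(x, w) weighted_quantile(x, w, 0.5)

#' Extract loops from an alignment path
#'
#' A loop is the expanded sequence of one complete repeat-unit traversal:
#' the stretch between two consecutive same-orientation visits of the anchor
#' node. Loops from reverse-orientation anchor visits are
#' reverse-complemented so all loops share a canonical orientation. Loops
#' outside `[0.5, 2] * approx_morph_size` are discarded and counted in the
#' `discarded` attribute.
#'
#' @param path an `alignment_path` (from [align_read()]).
#' @param anchor anchor node id.
#' @param approx_morph_size approximate repeat-unit size in bp.
#' @param aligner the [graph_aligner()] that produced the path.
#' @return list of loops (`read_id`, `ordinal`, `sequence`, `path`), with
#'   attribute `discarded` counting length-filtered loops.
#' @export
extract_loops <- function(path, anchor, approx_morph_size, aligner) {
  al <- aligner
  pe <- path$expansion %||% path_expand(al, path$path)
  # read position of each element start: anchored elements know it exactly;
  # gap-filled elements are interpolated along the expansion
  er0 <- path$elem_read0
  if (!is.null(er0) && anyNA(er0)) {
    known <- which(!is.na(er0))
    if (length(known) >= 1) {
      er0 <- stats::approx(pe$offsets[known], er0[known], xout = pe$offsets,
                           rule = 2, ties = "ordered")$y
    }
  }
  loops <- list()
  discarded <- 0L
  ordinal <- 0L
  for (orient in c("+", "-")) {
    occ <- which(path$path$id == anchor & path$path$o == orient)
    if (length(occ) < 2) next
    for (t in seq_len(length(occ) - 1)) {
      # a loop must start at an anchor visit the read actually covers: if
      # the path BEGINS inside the anchor node, that first visit's start
      # was never observed and the loop would contain unread graph sequence
      if (occ[t] == 1 && path$start_offset > al$anchor_k) next
      a <- pe$offsets[occ[t]]; b <- pe$offsets[occ[t + 1]]
      s <- substr(pe$seq, max(0, a) + 1, b)
      len <- nchar(s)
      if (len < 0.5 * approx_morph_size || len > 2 * approx_morph_size) {
        discarded <- discarded + 1L
        next
      }
      rseq <- NULL
      if (!is.null(er0) && !is.null(path$read_seq)) {
        r0 <- round(er0[occ[t]]); r1 <- round(er0[occ[t + 1]])
        if (!is.na(r0) && !is.na(r1) && r1 > r0) {
          rseq <- substr(path$read_seq, max(0, r0) + 1, r1)
        }
      }
      if (orient == "-") {
        s <- cpp_revcomp(s)
        if (!is.null(rseq)) rseq <- cpp_revcomp(rseq)
      }
      ordinal <- ordinal + 1L
      loops[[length(loops) + 1L]] <-
        list(read_id = path$read_id, ordinal = ordinal, sequence = s,
             read_sequence = rseq,
             path = path$path[occ[t]:occ[t + 1], , drop = FALSE])
    }
  }
  attr(loops, "discarded") <- discarded
  loops
}

#' Threshold-limited pairwise loop distances
#'
#' Computes all pairwise edit distances up to `limit` edits; entries above
#' the limit are `NA` ("exceeds"). Pairs sharing less than 5% of their
#' 15-mer sketches are marked exceeds without alignment, and identical
#' sequences are deduplicated before alignment, so cost scales with the
#' number of distinct loop sequences.
#'
#' @param loops list of loops (or character vector of sequences).
#' @param limit distance cap in edits (must be >= the rough-cluster
#'   threshold it will be used with).
#' @return symmetric numeric matrix with `NA` marking exceeded pairs.
#' @export
pairwise_distances <- function(loops, limit) {
  seqs <- if (is.character(loops)) loops else
    vapply(loops, `[[`, character(1), "sequence")
  n <- length(seqs)
  uniq <- unique(seqs)
  map <- match(seqs, uniq)
  Du <- cpp_pairwise_dist(uniq, as.double(limit), 0.05)
  D <- Du[map, map, drop = FALSE]
  dimnames(D) <- NULL
  D
}

#' Rough clustering by union-find
#'
#' Joins loop pairs whose edit distance is at most `max_rough_diff`; rough
#' clusters are the connected components.
#'
#' @param distances matrix from [pairwise_distances()].
#' @param max_rough_diff join threshold in edits.
#' @return list of integer index vectors (each sorted; clusters ordered by
#'   smallest member).
#' @export
rough_cluster <- function(distances, max_rough_diff) {
  n <- nrow(distances)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      js <- which(!is.na(distances[i, ]) & distances[i, ] <= max_rough_diff)
      for (j in js[js > i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  comps <- comps[order(as.integer(names(comps)))]
  names(comps) <- NULL
  lapply(comps, as.integer)
}

#' Estimate the DBSCAN epsilon from rough clusters
#'
#' Epsilon is the rounded mean of the finite pairwise distances within rough
#' clusters of size >= 2, floored at `min_epsilon`; with no such pair it is
#' `min_epsilon`. Well-separated morph families give a small epsilon (better
#' morph resolution); pooling divergent families inflates it.
#'
#' @param rough list of rough clusters (from [rough_cluster()]).
#' @param distances matrix from [pairwise_distances()].
#' @param min_epsilon lower bound in edits (>= 1).
#' @return epsilon in edits.
#' @export
estimate_epsilon <- function(rough, distances, min_epsilon = 1) {
  stopifnot(length(rough) >= 1, min_epsilon >= 1)
  vals <- numeric(0)
  for (cl in rough) {
    if (length(cl) < 2) next
    sub <- distances[cl, cl, drop = FALSE]
    v <- sub[upper.tri(sub)]
    vals <- c(vals, v[!is.na(v)])
  }
  if (length(vals) == 0) return(as.numeric(min_epsilon))
  max(min_epsilon, round(mean(vals)))
}

#' DBSCAN on precomputed distances
#'
#' Standard DBSCAN over the loop metric: a core point has at least
#' `min_pts` neighbours within `epsilon` (inclusive, counting itself);
#' clusters are connected components of core points, plus border points
#' (assigned to the lowest-id reachable cluster); everything else is noise.
#' `NA` distances are treated as exceeding epsilon.
#'
#' @param loops loop list (only its length is used).
#' @param distances matrix from [pairwise_distances()].
#' @param epsilon neighbourhood radius in edits (>= 1).
#' @param min_pts core-point threshold.
#' @return list with `clusters` (list of sorted index vectors, ordered by
#'   smallest core member), `noise` (sorted indices), `epsilon_used`.
#' @export
dbscan_cluster <- function(loops, distances, epsilon, min_pts) {
  stopifnot(epsilon >= 1)
  n <- nrow(distances)
  adj <- !is.na(distances) & distances <= epsilon
  diag(adj) <- TRUE
  deg <- rowSums(adj)
  core <- which(deg >= min_pts)
  assign <- rep(0L, n)
  cid <- 0L
  for (s in core) {
    if (assign[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    assign[s] <- cid
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      nb <- which(adj[x, ])
      for (y in nb) {
        if (assign[y] == 0L && y %in% core) {
          assign[y] <- cid
          queue <- c(queue, y)
        }
      }
    }
  }
  # border points: non-core within epsilon of a core; lowest cluster id wins
  for (x in seq_len(n)) {
    if (assign[x] != 0L || x %in% core) next
    nb_core <- intersect(which(adj[x, ]), core)
    if (length(nb_core)) assign[x] <- min(assign[nb_core])
  }
  clusters <- lapply(seq_len(cid), function(i) which(assign == i))
  noise <- which(assign == 0L)
  list(clusters = clusters, noise = noise, epsilon_used = epsilon)
}
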