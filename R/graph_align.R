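#' Prepare a graph aligner
#'
#' Precomputes everything needed to align reads to an allele graph: an exact
#' anchor k-mer index over expanded node sequences, oriented node lengths,
#' overlap expansions, adjacency lists and a shortest-path cache. Anchors use
#' expanded (not homopolymer-compressed) space so that noisy reads retain
#' exact seeds.
#'
#' Internally every oriented node (id, +/-) is an integer index
#' `2*id - 1` (+) or `2*id` (-), which keeps chaining and path search in
#' flat vectors.
#'
#' @param graph an `allele_graph`.
#' @param anchor_k anchor k-mer length (<= 31); default 17 so that reads
#'   with 5% errors still carry frequent exact seeds.
#' @param build_index build the anchor k-mer index (skip for walk-only use).
#' @return a `graph_aligner` object.
#' @export
graph_aligner <- function(graph, anchor_k = 17, build_index = TRUE) {
  stopifnot(inherits(graph, "allele_graph"))
  ids <- graph$nodes$id
  max_id <- max(ids)
  node_exp <- character(max_id)
  exp_len <- integer(max_id)
  for (i in seq_along(ids)) {
    node_exp[ids[i]] <- expand_node(graph, ids[i])
    exp_len[ids[i]] <- nchar(node_exp[ids[i]])
  }
  k <- graph$k
  n_oi <- 2L * max_id
  ov_oi <- integer(n_oi)   # expanded length of the leading k-1 overlap
  for (i in seq_along(ids)) {
    id <- ids[i]
    r <- pmax(1L, as.integer(graph$runs[[i]]))
    L <- length(r)
    ov <- min(k - 1L, L)
    ov_oi[2L * id - 1L] <- sum(r[seq_len(ov)])
    ov_oi[2L * id] <- sum(r[seq.int(L - ov + 1L, L)])
  }
  exp_oi <- exp_len[ceiling(seq_len(n_oi) / 2)]
  eff_oi <- exp_oi - ov_oi
  node_exp_oi <- character(n_oi)
  node_exp_oi[seq(1L, n_oi, by = 2L)] <- node_exp
  node_exp_oi[seq(2L, n_oi, by = 2L)] <- cpp_revcomp(node_exp)
  de <- directed_edges(graph)
  from_oi <- 2L * de$from - (de$from_o == "+")
  to_oi <- 2L * de$to - (de$to_o == "+")
  adj_to <- vector("list", n_oi)
  adj_cov <- vector("list", n_oi)
  for (j in seq_along(from_oi)) {
    adj_to[[from_oi[j]]] <- c(adj_to[[from_oi[j]]], to_oi[j])
    adj_cov[[from_oi[j]]] <- c(adj_cov[[from_oi[j]]], de$cov[j])
  }
  # deterministic neighbour order: by coverage desc, then target index
  for (u in seq_len(n_oi)) {
    if (length(adj_to[[u]]) > 1) {
      o <- order(-adj_cov[[u]], adj_to[[u]])
      adj_to[[u]] <- adj_to[[u]][o]
      adj_cov[[u]] <- adj_cov[[u]][o]
    }
  }
  # collapsed tandem repeats are traversed several times per copy; their
  # coverage stands far above the rest and anchors on them carry no phase
  repeat_node <- logical(max_id)
  repeat_node[ids] <- collapsed_repeat_nodes(graph$nodes)
  structure(list(graph = graph, anchor_k = as.integer(anchor_k),
                 repeat_node = repeat_node,
                 index = if (build_index)
                   cpp_anchor_index(node_exp, as.integer(anchor_k)),
                 node_exp = node_exp, node_exp_oi = node_exp_oi,
                 exp_len = exp_len,
                 n_oi = n_oi, ov_oi = ov_oi, exp_oi = exp_oi, eff_oi = eff_oi,
                 adj_to = adj_to, adj_cov = adj_cov,
                 adj_ptr = cpp_graph_adj(adj_to, eff_oi, as.numeric(ov_oi),
                                         cutoff = 6000),
                 gap_ptr = cpp_gap_graph(adj_to, node_exp_oi,
                                         as.integer(ov_oi))),
            class = "graph_aligner")
}

oi_of <- function(id, o) 2L * id - (o == "+")
oi_id <- function(oi) as.integer(ceiling(oi / 2))
oi_o <- function(oi) ifelse(oi %% 2L == 1L, "+", "-")

# oriented node sequence
oi_seq <- function(al, oi) al$node_exp_oi[oi]

# Dijkstra from the end of oriented node `src`; dist[v] = cumulative
# effective expanded length of entered nodes (target included); `reentry`
# is the shortest strictly positive cycle back into src. Results are cached
# inside the adjacency object.
dijkstra_from <- function(al, src, cutoff = 6000) {
  cpp_dijkstra(al$adj_ptr, src)
}

# convert a raw forward-coordinate anchor position to oriented coordinates
oriented_pos <- function(al, id, orient, raw_pos, ak) {
  if (orient > 0) raw_pos else al$exp_len[id] - raw_pos - ak
}

#' Anchor a read against the allele graph
#'
#' Reports every exact shared `anchor_k`-mer between the read and the
#' expanded node sequences, in both orientations, capped at 5 hits per read
#' position.
#'
#' @param read a sequence string (or single-row record data.frame).
#' @param aligner a [graph_aligner()] (an `allele_graph` is also accepted
#'   and promoted, rebuilding the index each call).
#' @param anchor_k anchor k-mer length when `aligner` is a bare graph.
#' @return data.frame with `read_pos`, `node`, `node_pos` (0-based, node
#'   forward coordinates) and `orient` (+1/-1).
#' @export
anchor_read <- function(read, aligner, anchor_k = 17) {
  if (inherits(aligner, "allele_graph")) aligner <- graph_aligner(aligner, anchor_k)
  seq <- if (is.data.frame(read)) read$seq[1] else as.character(read)
  cpp_anchor_raw(toupper(seq), aligner$index, 5L)
}

# enumerate candidate paths (integer vectors of oriented indices, target
# included) from the successors of `from` to `to`, cumulative effective
# length <= budget; bounded search.
enumerate_gap_paths <- function(al, from, to, budget,
                                max_paths = 32L, max_steps = 4000L) {
  cpp_enum_gap_paths(al$adj_ptr, from, to, budget,
                     as.integer(max_paths), as.integer(max_steps))
}

# shortest path (oriented indices, target included, source excluded) from
# the Dijkstra tree; NULL if unreachable within the cached cutoff
shortest_gap_path <- function(al, from, to) {
  dj <- dijkstra_from(al, from, cutoff = 6000)
  if (to == from) {
    if (!is.finite(dj$reentry)) return(NULL)
    u <- dj$reentry_via
    path <- integer(0)
    while (!is.na(u) && u != from) { path <- c(u, path); u <- dj$parent[u] }
    return(c(path, to))
  }
  if (!is.finite(dj$dist[to])) return(NULL)
  path <- integer(0)
  u <- to
  while (!is.na(u) && u != from) { path <- c(u, path); u <- dj$parent[u] }
  path
}

# expansion of a path of oriented indices with k-1 compressed overlaps
# stripped; offsets[e] is the position of element e's oriented coordinate 0
# in the expansion.
path_expand_oi <- function(al, ois) {
  s <- al$node_exp_oi[ois]
  ov <- al$ov_oi[ois]
  ov[1] <- 0L
  contrib <- al$exp_oi[ois] - ov
  cum <- cumsum(contrib)
  offsets <- c(0, cum[-length(cum)]) - ov
  offsets[1] <- 0
  pieces <- substring(s, ov + 1L)
  list(seq = paste(pieces, collapse = ""), offsets = offsets)
}

# public-shaped helper kept for loop extraction: elements is data.frame(id, o)
path_expand <- function(al, elements) {
  path_expand_oi(al, oi_of(elements$id, elements$o))
}

#' Align a read to the allele graph
#'
#' Anchors are collapsed into colinear diagonal segments, chained by
#' increasing read position with graph-reachability checks and a gap-length
#' difference penalty, and inter-segment gaps are threaded through candidate
#' graph paths (bounded search, best edit distance against the read
#' substring). Maximal chains with identity >= `min_identity` are emitted;
#' one read may yield several disjoint paths, and secondary chains mostly
#' covered by a better one are suppressed.
#'
#' @param read sequence string or single-row record data.frame.
#' @param aligner a [graph_aligner()].
#' @param read_id id stored on the result.
#' @param min_identity identity floor for emitted paths (default 0.75).
#' @return list of `alignment_path` objects (possibly empty): each has
#'   `read_id`, `path` (data.frame id, o), `start_offset`, `end_offset`
#'   (expanded, oriented coordinates in first/last node), `identity`,
#'   `read_interval` (half-open).
#' @export
align_read <- function(read, aligner, read_id = NULL, min_identity = 0.75) {
  if (inherits(aligner, "allele_graph")) aligner <- graph_aligner(aligner)
  al <- aligner
  seq <- if (is.data.frame(read)) read$seq[1] else as.character(read)
  if (is.null(read_id)) {
    read_id <- if (is.data.frame(read)) read$id[1] else "read"
  }
  seq <- toupper(seq)
  ak <- al$anchor_k
  segs <- cpp_anchor_segments(seq, al$index, 12L, 50L, 500L)
  if (nrow(segs) == 0) return(list())
  # segments made of highly ambiguous k-mers, or lying on collapsed-repeat
  # nodes, carry no positional information and mis-pin the chain inside
  # repeat cycles; drop them and let base-level gap threading choose the
  # traversal count instead
  informative <- segs$weight / segs$n_anchors >= 0.25 &
    !al$repeat_node[segs$node]
  if (any(informative)) segs <- segs[informative, , drop = FALSE]
  segs$o <- ifelse(segs$orient > 0, "+", "-")
  segs$oi <- oi_of(segs$node, segs$o)
  q_start <- integer(nrow(segs)); q_end <- integer(nrow(segs))
  for (r in seq_len(nrow(segs))) {
    q_start[r] <- oriented_pos(al, segs$node[r], segs$orient[r],
                               segs$node_start[r], ak)
    q_end[r] <- oriented_pos(al, segs$node[r], segs$orient[r],
                             segs$node_end[r], ak)
  }
  segs$q_start <- q_start; segs$q_end <- q_end
  ord <- order(segs$read_start, segs$read_end, segs$node, segs$o)
  segs <- segs[ord, , drop = FALSE]
  rownames(segs) <- NULL
  ns <- nrow(segs)
  used <- rep(FALSE, ns)
  out <- list()
  max_gap <- 3000
  # plain vectors for the DP
  s_rs <- segs$read_start; s_re <- segs$read_end
  s_oi <- segs$oi; s_qs <- segs$q_start; s_qe <- segs$q_end
  s_na <- segs$weight
  s_tail <- al$exp_oi[s_oi] - (s_qe + ak)

  repeat {
    idx <- which(!used)
    if (length(idx) == 0) break
    dp <- cpp_chain_segments(al$adj_ptr, s_rs, s_re, s_oi, s_qs, s_qe, s_na,
                             s_tail, al$exp_oi[s_oi],
                             as.integer(!used), ak, max_gap)
    score <- dp$score; pred <- dp$pred; link_code <- dp$link
    link <- c(NA_character_, "cont", "path")[link_code + 1L]
    best <- idx[which.max(score[idx])]
    chain <- integer(0); cur <- best
    while (cur != 0L) { chain <- c(cur, chain); cur <- pred[cur] }
    used[chain] <- TRUE
    if (sum(s_na[chain]) < 8) break # best remaining chain is noise: stop
    if (sum(s_na[chain]) >= 8) {
      ap <- build_alignment_path(al, seq, segs, chain, link, read_id,
                                 min_identity)
      if (!is.null(ap)) {
        dup <- any(vapply(out, function(p) {
          ov <- min(p$read_interval[2], ap$read_interval[2]) -
            max(p$read_interval[1], ap$read_interval[1])
          ov > 0.5 * (ap$read_interval[2] - ap$read_interval[1])
        }, logical(1)))
        if (!dup) out[[length(out) + 1L]] <- ap
      }
    }
    if (sum(s_na[!used]) < 15) break
  }
  out
}

# assemble the node path for a chain of segment indices and score it
build_alignment_path <- function(al, seq, segs, chain, link, read_id,
                                 min_identity) {
  ak <- al$anchor_k
  ois <- segs$oi[chain[1]]
  elem_of <- c(1L)
  # read position where each element's oriented coordinate 0 sits (NA for
  # gap-filled elements); lets loop extraction recover read-space intervals
  elem_read0 <- segs$read_start[chain[1]] - segs$q_start[chain[1]]
  ok <- TRUE
  for (t in seq_along(chain)[-1]) {
    ii <- chain[t - 1]; jj <- chain[t]
    if (identical(link[jj], "cont")) {
      elem_of <- c(elem_of, length(ois))
      next
    }
    gap_r <- segs$read_start[jj] - (segs$read_end[ii] + ak)
    # base-level alignment of the read gap substring into the graph,
    # anchored exactly at the flanking anchor k-mers
    rs <- segs$read_end[ii] + ak + 1
    re <- segs$read_start[jj]
    read_gap <- if (re >= rs) substr(seq, rs, re) else ""
    pick <- NULL
    gl <- nchar(read_gap)
    # stage 1: enumerate candidate paths shortest-first and rank them by
    # edit distance against the read gap (cheap, adequate for gaps holding
    # few variant sites)
    tail_i <- al$exp_oi[segs$oi[ii]] - (segs$q_end[ii] + ak)
    budget <- max(gl - tail_i, 0) + 80
    cands <- enumerate_gap_paths(al, segs$oi[ii], segs$oi[jj], budget,
                                 max_paths = 16L)
    best_d <- Inf
    for (cnd in cands) {
      full <- c(segs$oi[ii], cnd)
      pe <- path_expand_oi(al, full)
      gs_start <- segs$q_end[ii] + ak
      gs_end <- pe$offsets[length(full)] + segs$q_start[jj]
      gap_seq <- if (gs_end >= gs_start + 1) {
        substr(pe$seq, gs_start + 1, gs_end)
      } else ""
      d <- cpp_edit_distance(read_gap, gap_seq, -1)
      if (d < best_d) { best_d <- d; pick <- cnd }
    }
    # stage 2: if no candidate explains the read gap, run the base-level
    # read-to-graph DP with the enumeration's score as its upper bound
    # (branch-and-bound: only repeat cycles and multi-bubble stretches pay)
    if (gl <= 400 && best_d > 0.2 * gl + 8) {
      limit <- as.integer(min(best_d - 1, 0.25 * gl + 20))
      if (limit >= 0) {
        res <- cpp_align_gap(al$gap_ptr, segs$oi[ii], segs$q_end[ii] + ak,
                             segs$oi[jj], segs$q_start[jj], read_gap, limit,
                             max_states = 200000L)
        if (!identical(res$dist, -1L)) pick <- res$path
      }
    }
    if (is.null(pick)) {
      # fall back to the shortest path from the Dijkstra tree
      sp <- shortest_gap_path(al, segs$oi[ii], segs$oi[jj])
      if (is.null(sp)) { ok <- FALSE; break }
      pick <- sp
    }
    ois <- c(ois, pick)
    elem_read0 <- c(elem_read0, rep(NA_real_, length(pick) - 1L),
                    segs$read_start[jj] - segs$q_start[jj])
    elem_of <- c(elem_of, length(ois))
  }
  if (!ok) return(NULL)
  pe <- path_expand_oi(al, ois)
  first <- chain[1]; last <- chain[length(chain)]
  p_start <- pe$offsets[1] + segs$q_start[first]
  p_end <- pe$offsets[elem_of[length(elem_of)]] + segs$q_end[last] + ak
  r_start <- segs$read_start[first]
  r_end <- segs$read_end[last] + ak
  path_seq <- substr(pe$seq, p_start + 1, p_end)
  read_seq <- substr(seq, r_start + 1, r_end)
  maxlen <- max(nchar(path_seq), nchar(read_seq))
  if (maxlen == 0) return(NULL)
  d <- cpp_edit_distance(read_seq, path_seq, ceiling((1 - min_identity) * maxlen))
  if (is.na(d)) return(NULL)
  identity <- 1 - d / maxlen
  structure(list(read_id = read_id,
                 path = data.frame(id = oi_id(ois), o = oi_o(ois),
                                   stringsAsFactors = FALSE),
                 start_offset = segs$q_start[first],
                 end_offset = segs$q_end[last] + ak,
                 identity = identity,
                 read_interval = c(r_start, r_end),
                 expansion = pe,
                 elem_read0 = elem_read0,
                 read_seq = seq),
            class = "alignment_path")
}

#' @export
print.alignment_path <- function(x, ...) {
  cat(sprintf("alignment_path: read %s [%d,%d) over %d nodes, identity %.4f\n",
              x$read_id, x$read_interval[1], x$read_interval[2],
              nrow(x$path), x$identity))
  invisible(x)
}

# every consecutive node pair in a path must be a graph edge
validate_alignment_path <- function(al, ap) {
  ois <- oi_of(ap$path$id, ap$path$o)
  if (length(ois) < 2) return(TRUE)
  for (i in seq_len(length(ois) - 1)) {
    if (!(ois[i + 1] %in% al$adj_to[[ois[i]]])) return(FALSE)
  }
  TRUE
}
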