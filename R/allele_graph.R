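#' Homopolymer compression
#'
#' Collapses runs of identical bases to a single base and records the run
#' lengths, so that [hpc_expand()] with the recorded lengths is an exact
#' inverse. Runs of N are dropped with a warning (real reads contain N but
#' the graph is built over A/C/G/T only).
#'
#' @param bases a single sequence string.
#' @return list with elements `compressed` (string with no two equal adjacent
#'   characters) and `runs` (integer run length per compressed position).
#' @export
hpc_compress <- function(bases) {
  bases <- toupper(as.character(bases))
  if (grepl("N", bases, fixed = TRUE)) {
    warning("N runs dropped before homopolymer compression")
    bases <- gsub("N", "", bases, fixed = TRUE)
  }
  r <- cpp_hpc_compress(bases)
  list(compressed = r$compressed[[1]], runs = as.integer(r$runs[[1]]))
}

#' @rdname hpc_compress
#' @param hpc output of [hpc_compress()], or any compressed string.
#' @param runs integer run-length estimates, one per compressed position.
#' @export
hpc_expand <- function(hpc, runs = NULL) {
  if (is.list(hpc)) { runs <- hpc$runs; hpc <- hpc$compressed }
  cpp_hpc_expand(hpc, as.integer(runs))
}

#' Build the allele graph from accurate reads
#'
#' Reads are homopolymer-compressed and a de Bruijn graph over canonical
#' k-mers with multiplicity >= `solid_min` is built and compacted into
#' unitigs. Per-position run lengths are accumulated across supporting reads
#' and summarised by their median, which is what [expand_node()] uses to
#' restore homopolymer runs. Node ids are assigned by sorted node sequence,
#' so construction does not depend on read order.
#'
#' @param reads data.frame of sequence records (see [read_sequences()]) or a
#'   character vector of sequences.
#' @param k odd k-mer size in compressed space.
#' @param solid_min minimum canonical k-mer multiplicity; `"auto"` scales
#'   with coverage as `max(2, round(median solid-candidate count / 6))`.
#' @return an object of class `allele_graph` with fields `k`, `nodes`
#'   (id, seq in compressed space, cov, len in expanded space), `runs`
#'   (per-node integer run lengths) and `edges`
#'   (from, from_o, to, to_o, cov; overlap is always k-1 compressed bases).
#' @export
build_allele_graph <- function(reads, k = 101, solid_min = 5) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  if (k %% 2 == 0) stop("k must be odd")
  if (length(seqs) == 0) stage_stop("allele_graph", "no input reads")
  seqs <- toupper(seqs)
  seqs <- gsub("N", "", seqs, fixed = TRUE)
  hp <- cpp_hpc_compress(seqs)
  comp <- unlist(hp$compressed)
  if (identical(solid_min, "auto")) {
    cnt <- cpp_count_kmers(comp, as.integer(k))$count
    cand <- cnt[cnt >= 2]
    solid_min <- if (length(cand)) max(2, round(stats::median(cand) / 6)) else 2
  }
  res <- tryCatch(
    cpp_build_dbg(comp, hp$runs, as.integer(k), as.integer(solid_min)),
    error = function(e) stage_stop("allele_graph", conditionMessage(e),
                                   "lower solid_min or check read accuracy"))
  n <- length(res$seq)
  nodes <- data.frame(id = seq_len(n), seq = res$seq, cov = res$cov,
                      stringsAsFactors = FALSE)
  nodes$len <- vapply(seq_len(n), function(i)
    sum(pmax(1L, as.integer(res$runs[[i]]))), numeric(1))
  g <- structure(list(
    k = as.integer(k), nodes = nodes, runs = res$runs,
    edges = data.frame(from = res$edge_from, from_o = as.character(res$edge_from_o),
                       to = res$edge_to, to_o = as.character(res$edge_to_o),
                       cov = res$edge_cov, stringsAsFactors = FALSE)),
    class = "allele_graph")
  g
}

#' Expanded (run-length-decoded) sequence of a node
#'
#' @param graph an `allele_graph`.
#' @param id node id.
#' @param orient `"+"` for the stored strand, `"-"` for its reverse
#'   complement.
#' @return the expanded sequence string.
#' @export
expand_node <- function(graph, id, orient = "+") {
  i <- match(id, graph$nodes$id)
  if (is.na(i)) stop("no node with id ", id)
  s <- cpp_hpc_expand(graph$nodes$seq[i], as.integer(graph$runs[[i]]))
  if (orient == "-") cpp_revcomp(s) else s
}

#' @export
print.allele_graph <- function(x, ...) {
  cat(sprintf("allele_graph: %d nodes, %d edges, k=%d (compressed space)\n",
              nrow(x$nodes), nrow(x$edges), x$k))
  if (nrow(x$nodes)) {
    cat(sprintf("  total expanded length %.0f bp, coverage %.1f-%.1f\n",
                sum(x$nodes$len), min(x$nodes$cov), max(x$nodes$cov)))
  }
  invisible(x)
}

flip_orient <- function(o) ifelse(o == "+", "-", "+")

# Directed half-edge view of the normalized edge list: each stored edge
# (from,fo) -> (to,to_o) also stands for (to, flip(to_o)) -> (from, flip(fo)).
directed_edges <- function(graph) {
  ed <- graph$edges
  if (is.null(ed) || nrow(ed) == 0) {
    return(data.frame(from = integer(), from_o = character(),
                      to = integer(), to_o = character(), cov = numeric(),
                      stringsAsFactors = FALSE))
  }
  fwd <- ed
  rev <- data.frame(from = ed$to, from_o = flip_orient(ed$to_o),
                    to = ed$from, to_o = flip_orient(ed$from_o),
                    cov = ed$cov, stringsAsFactors = FALSE)
  both <- rbind(fwd, rev)
  both[!duplicated(both[, c("from", "from_o", "to", "to_o")]), , drop = FALSE]
}

# successors of an oriented node as a data.frame(to, to_o, cov)
out_edges <- function(dir_edges, node, orient) {
  dir_edges[dir_edges$from == node & dir_edges$from_o == orient,
            c("to", "to_o", "cov"), drop = FALSE]
}

normalize_edges <- function(ed) {
  if (nrow(ed) == 0) return(ed)
  oi <- function(o) ifelse(o == "+", 0L, 1L)
  a <- cbind(ed$from, oi(ed$from_o), ed$to, oi(ed$to_o))
  b <- cbind(ed$to, 1L - oi(ed$to_o), ed$from, 1L - oi(ed$from_o))
  swap <- (b[, 1] < a[, 1]) |
    (b[, 1] == a[, 1] & b[, 2] < a[, 2]) |
    (b[, 1] == a[, 1] & b[, 2] == a[, 2] & b[, 3] < a[, 3]) |
    (b[, 1] == a[, 1] & b[, 2] == a[, 2] & b[, 3] == a[, 3] & b[, 4] < a[, 4])
  out <- ed
  out$from[swap] <- ed$to[swap]
  out$from_o[swap] <- flip_orient(ed$to_o[swap])
  out$to[swap] <- ed$from[swap]
  out$to_o[swap] <- flip_orient(ed$from_o[swap])
  key <- paste(out$from, out$from_o, out$to, out$to_o)
  out <- out[!duplicated(key), , drop = FALSE]
  out[order(out$from, out$from_o, out$to, out$to_o), , drop = FALSE]
}

# reassign node ids by sorted node sequence; remap edges; drop orphan edges
renumber_graph <- function(g) {
  nd <- g$nodes
  ord <- order(nd$seq)
  old_id <- nd$id[ord]
  map <- stats::setNames(seq_along(old_id), old_id)
  nd <- nd[ord, , drop = FALSE]
  nd$id <- seq_len(nrow(nd))
  rownames(nd) <- NULL
  runs <- g$runs[ord]
  ed <- g$edges
  keep <- ed$from %in% old_id & ed$to %in% old_id
  ed <- ed[keep, , drop = FALSE]
  ed$from <- as.integer(map[as.character(ed$from)])
  ed$to <- as.integer(map[as.character(ed$to)])
  g$nodes <- nd
  g$runs <- runs
  g$edges <- normalize_edges(ed)
  rownames(g$edges) <- NULL
  g
}

#' Clean an allele graph
#'
#' Removes nodes below a coverage floor, then short low-coverage dead-end
#' unitigs (tips), and re-compacts non-branching paths so the unitig
#' maximality invariant is restored.
#'
#' @param graph an `allele_graph`.
#' @param min_node_coverage nodes with mean k-mer coverage below this are
#'   removed.
#' @param max_tip_length dead-end nodes shorter than this (expanded bp) with
#'   coverage below 25% of their best neighbour are removed.
#' @return the cleaned `allele_graph`.
#' @export
clean_graph <- function(graph, min_node_coverage = 2, max_tip_length = 2 * graph$k) {
  g <- graph
  # bounded rounds: tip removal and re-compaction can oscillate on degenerate
  # structures, and repeated rounds beyond a few have no practical effect
  for (round in 1:8) {
    changed <- FALSE
    nd <- g$nodes
    drop <- nd$id[nd$cov < min_node_coverage]
    if (length(drop)) changed <- TRUE
    de <- directed_edges(g)
    neigh_cov <- function(id) {
      nb <- unique(c(de$to[de$from == id], de$from[de$to == id]))
      nb <- setdiff(nb, id)
      if (length(nb) == 0) return(Inf)
      max(nd$cov[match(nb, nd$id)])
    }
    for (id in setdiff(nd$id, drop)) {
      n_out <- nrow(out_edges(de, id, "+"))
      n_in <- nrow(out_edges(de, id, "-"))
      is_tip <- (n_out == 0 || n_in == 0) && (n_out + n_in > 0)
      if (is_tip && nd$len[match(id, nd$id)] < max_tip_length &&
          nd$cov[match(id, nd$id)] < 0.25 * neigh_cov(id)) {
        drop <- c(drop, id)
        changed <- TRUE
      }
    }
    if (length(drop)) {
      keep <- !(g$nodes$id %in% drop)
      if (!any(keep)) {
        stage_stop("clean_graph", "cleaning removed every node",
                   "lower min_node_coverage / max_tip_length thresholds")
      }
      g$runs <- g$runs[keep]
      g$nodes <- g$nodes[keep, , drop = FALSE]
      ed <- g$edges
      g$edges <- ed[!(ed$from %in% drop) & !(ed$to %in% drop), , drop = FALSE]
    }
    g <- compact_graph(g)
    if (!changed) break
  }
  renumber_graph(g)
}

# node sequence/runs in a given orientation (compressed space)
oriented_parts <- function(g, id, orient) {
  i <- match(id, g$nodes$id)
  s <- g$nodes$seq[i]
  r <- as.integer(g$runs[[i]])
  if (orient == "-") {
    s <- cpp_revcomp(s)
    r <- rev(r)
  }
  list(seq = s, runs = r)
}

# merge non-branching node chains; overlap k-1 compressed. Mergeable edges
# (u,ou)->(v,ov) — unique out-edge of (u,ou) and unique in-edge of (v,ov)
# with u != v — form disjoint chains that are merged in one pass.
compact_graph <- function(g) {
  k <- g$k
  repeat {
    de <- directed_edges(g)
    if (nrow(de) == 0) break
    okey <- paste0(de$from, de$from_o)
    outdeg <- table(okey)
    from_key <- paste0(de$from, de$from_o)
    into_key <- paste0(de$to, flip_orient(de$to_o)) # reverse-side out-degree
    mergeable <- de$from != de$to &
      as.integer(outdeg[from_key]) == 1L &
      as.integer(outdeg[into_key]) == 1L
    me <- de[mergeable, , drop = FALSE]
    if (nrow(me) == 0) break
    # successor map over oriented nodes
    succ <- stats::setNames(paste0(me$to, me$to_o), paste0(me$from, me$from_o))
    # drop chains that loop (full cycles stay as they are)
    heads <- setdiff(names(succ), paste0(me$to, me$to_o))
    # also break cycles arbitrarily: any succ entry not reachable from a head
    reached <- character(0)
    chains <- list()
    for (h in heads) {
      ch <- h
      cur <- h
      while (cur %in% names(succ)) {
        nxt <- succ[[cur]]
        if (nxt %in% ch) break
        ch <- c(ch, nxt)
        cur <- nxt
      }
      chains[[length(chains) + 1L]] <- ch
      reached <- c(reached, ch)
    }
    if (length(chains) == 0) break
    # merge each chain into a single node
    ed <- g$edges
    merged_any <- FALSE
    for (ch in chains) {
      ids <- as.integer(sub("[+-]$", "", ch))
      ors <- substring(ch, nchar(ch), nchar(ch))
      if (anyDuplicated(ids)) next # node visited in both strands: leave as is
      # every chain also appears as its reverse-complement twin; skip the
      # twin once the first copy has been merged
      if (!all(ids %in% g$nodes$id)) next
      merged_any <- TRUE
      parts <- lapply(seq_along(ids), function(t) oriented_parts(g, ids[t], ors[t]))
      seqs <- vapply(parts, `[[`, character(1), "seq")
      runs <- lapply(parts, `[[`, "runs")
      new_seq <- paste0(seqs[1], paste(vapply(seqs[-1], function(s)
        substr(s, k, nchar(s)), character(1)), collapse = ""))
      new_runs <- c(runs[[1]], unlist(lapply(runs[-1], function(r)
        r[k:length(r)])))
      w <- vapply(seqs, nchar, numeric(1)) - k + 1
      covs <- g$nodes$cov[match(ids, g$nodes$id)]
      new_cov <- sum(covs * w) / sum(w)
      flipped <- FALSE
      rc_seq <- cpp_revcomp(new_seq)
      if (rc_seq < new_seq) { new_seq <- rc_seq; new_runs <- rev(new_runs); flipped <- TRUE }
      new_id <- max(g$nodes$id) + 1L
      # remove the chain's own consecutive-pair edges (either stored direction)
      pair_keys <- paste0(ch[-length(ch)], ">", ch[-1])
      key_fwd <- paste0(ed$from, ed$from_o, ">", ed$to, ed$to_o)
      key_rev <- paste0(ed$to, flip_orient(ed$to_o), ">",
                        ed$from, flip_orient(ed$from_o))
      ed <- ed[!(key_fwd %in% pair_keys | key_rev %in% pair_keys), , drop = FALSE]
      # rewire remaining edges touching chain ends
      head_id <- ids[1]; head_or <- ors[1]
      tail_id <- ids[length(ids)]; tail_or <- ors[length(ors)]
      map_end <- function(side_id, side_o) {
        # returns c(new_id, new_o) or NULL
        hit_head <- side_id == head_id
        hit_tail <- side_id == tail_id
        if (!hit_head && !hit_tail) return(NULL)
        # orientation relative to chain direction
        if (hit_head) pre <- if (side_o == head_or) "+" else "-"
        else pre <- if (side_o == tail_or) "+" else "-"
        o <- if (flipped) flip_orient(pre) else pre
        c(new_id, o)
      }
      for (j in seq_len(nrow(ed))) {
        m1 <- map_end(ed$from[j], ed$from_o[j])
        if (!is.null(m1)) { ed$from[j] <- as.integer(m1[1]); ed$from_o[j] <- m1[2] }
        m2 <- map_end(ed$to[j], ed$to_o[j])
        if (!is.null(m2)) { ed$to[j] <- as.integer(m2[1]); ed$to_o[j] <- m2[2] }
      }
      keep <- !(g$nodes$id %in% ids)
      g$runs <- c(g$runs[keep], list(as.integer(new_runs)))
      g$nodes <- rbind(g$nodes[keep, , drop = FALSE],
                       data.frame(id = new_id, seq = new_seq, cov = new_cov,
                                  len = sum(pmax(1L, as.integer(new_runs))),
                                  stringsAsFactors = FALSE))
    }
    g$edges <- normalize_edges(ed)
    if (!merged_any) break
  }
  g
}

# consistency checks used by tests
validate_graph <- function(g) {
  stopifnot(inherits(g, "allele_graph"))
  nd <- g$nodes
  stopifnot(!anyDuplicated(nd$id), all(nchar(nd$seq) >= g$k))
  stopifnot(length(g$runs) == nrow(nd))
  for (i in seq_len(nrow(nd))) {
    stopifnot(length(g$runs[[i]]) == nchar(nd$seq[i]))
    stopifnot(!grepl("(.)\\1", nd$seq[i])) # no two equal adjacent characters
  }
  de <- directed_edges(g)
  k <- g$k
  for (j in seq_len(nrow(de))) {
    su <- oriented_parts(g, de$from[j], de$from_o[j])$seq
    sv <- oriented_parts(g, de$to[j], de$to_o[j])$seq
    stopifnot(substr(su, nchar(su) - k + 2, nchar(su)) == substr(sv, 1, k - 1))
  }
  invisible(TRUE)
}
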