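#' Medoid of a loop cluster
#'
#' The loop minimizing total distance to the other members; distance entries
#' that exceeded the pairwise limit are computed on demand. Ties go to the
#' lowest index.
#'
#' @param cluster integer indices of the cluster members.
#' @param loops loop list (or character vector of sequences).
#' @param distances pairwise distance matrix (possibly with `NA` entries).
#' @return index (into `loops`) of the medoid.
#' @export
medoid <- function(cluster, loops, distances) {
  stopifnot(length(cluster) >= 1)
  seqs <- if (is.character(loops)) loops else
    vapply(loops, `[[`, character(1), "sequence")
  if (length(cluster) == 1) return(cluster[1])
  sub <- distances[cluster, cluster, drop = FALSE]
  nas <- which(is.na(sub), arr.ind = TRUE)
  # on-demand entries are computed up to a generous cap; anything beyond it
  # enters the totals at the cap, which cannot change the argmin in practice
  # (such pairs are far outside the cluster's own scale)
  cap <- max(2 * max(0, sub[!is.na(sub)]), 500)
  for (r in seq_len(nrow(nas))) {
    i <- nas[r, 1]; j <- nas[r, 2]
    if (i < j) {
      d <- cpp_edit_distance(seqs[cluster[i]], seqs[cluster[j]], cap)
      if (is.na(d)) d <- cap + 1
      sub[i, j] <- d; sub[j, i] <- d
    }
  }
  tot <- rowSums(sub)
  cluster[order(tot, seq_along(cluster))][1]
}

#' Polish a consensus against its cluster loops
#'
#' Iterative pileup-majority polishing: every loop is globally aligned to
#' the current consensus (band sized from a prior bit-parallel distance),
#' per-column base/gap observations are stacked, and each column is replaced
#' by its majority (ties keep the current base); majority insertions are
#' applied between columns. Stops at a fixed point or after `max_rounds`.
#' Identical loops are collapsed and weighted, so cost scales with distinct
#' sequences.
#'
#' @param seed_seq starting consensus (e.g. the medoid sequence).
#' @param cluster_loops character vector (or loop list) of member sequences.
#' @param max_rounds maximum polishing rounds (default 5).
#' @return polished consensus sequence.
#' @export
polish <- function(seed_seq, cluster_loops, max_rounds = 5) {
  seqs <- if (is.character(cluster_loops)) cluster_loops else
    vapply(cluster_loops, `[[`, character(1), "sequence")
  stopifnot(length(seqs) >= 1)
  tab <- table(seqs)
  useqs <- names(tab)
  w <- as.numeric(tab)
  cons <- seed_seq
  for (round in seq_len(max_rounds)) {
    new_cons <- polish_round(cons, useqs, w)
    if (identical(new_cons, cons)) return(cons)
    cons <- new_cons
  }
  if (max_rounds > 1) warning("polishing did not converge in ", max_rounds,
                              " rounds")
  cons
}

polish_round <- function(cons, useqs, w) {
  L <- nchar(cons)
  cons_chars <- strsplit(cons, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  votes <- matrix(0, nrow = 5, ncol = L,
                  dimnames = list(c(bases, "-"), NULL))
  ins <- vector("list", L + 1) # named numeric: inserted string -> weight
  ins_tot <- numeric(L + 1)
  total_w <- sum(w)
  add_ins <- function(slot, key, weight) {
    cur <- ins[[slot]]
    if (is.null(cur)) cur <- numeric(0)
    cur[key] <- (if (key %in% names(cur)) cur[[key]] else 0) + weight
    ins[[slot]] <<- cur
    ins_tot[slot] <<- ins_tot[slot] + weight
  }
  for (s in seq_along(useqs)) {
    b <- useqs[s]
    d <- cpp_edit_distance(cons, b, -1)
    aln <- cpp_align_global(cons, b, band = as.integer(d + 16))
    ops <- strsplit(aln$ops, "", fixed = TRUE)[[1]]
    bchars <- strsplit(b, "", fixed = TRUE)[[1]]
    is_i <- ops == "I"
    i_idx <- cumsum(!is_i)              # consensus column per op (0 before col 1)
    j_idx <- cumsum(ops != "D")         # position in b per op
    mx <- which(ops == "M" | ops == "X")
    if (length(mx)) {
      cells <- cbind(match(bchars[j_idx[mx]], rownames(votes)), i_idx[mx])
      votes[cells] <- votes[cells] + w[s]
    }
    dd <- which(ops == "D")
    if (length(dd)) votes[5L, i_idx[dd]] <- votes[5L, i_idx[dd]] + w[s]
    ii <- which(is_i)
    if (length(ii)) {
      grp <- cumsum(!is_i)[ii]          # insertions grouped by preceding column
      strs <- vapply(split(bchars[j_idx[ii]], grp), paste, character(1),
                     collapse = "")
      slots <- as.integer(names(strs)) + 1L
      for (t in seq_along(strs)) add_ins(slots[t], strs[t], w[s])
    }
  }
  out <- character(2L * L + 1L)
  for (i in seq_len(L + 1L)) {
    # insertion before column i: majority among inserted strings and ""
    iv <- ins[[i]]
    if (!is.null(iv) && length(iv)) {
      empty_w <- total_w - ins_tot[i]
      best <- which.max(iv)
      others <- if (length(iv) > 1) max(iv[-best]) else 0
      if (iv[best] > empty_w && iv[best] > others) {
        out[2L * i - 1L] <- names(iv)[best]
      }
    }
    if (i <= L) {
      v <- votes[, i]
      mx <- max(v)
      winners <- rownames(votes)[v == mx]
      pick <- if (length(winners) == 1) winners else
        if (cons_chars[i] %in% winners) cons_chars[i] else winners[1]
      out[2L * i] <- if (pick == "-") "" else pick
    }
  }
  paste(out, collapse = "")
}

#' Genome-wide consensus walk
#'
#' Greedy heaviest walk over the allele graph: starting from the anchor
#' node, repeatedly follow the highest-coverage outgoing edge (ties broken
#' by the lowest node id, then `+` orientation) until the anchor is
#' re-entered or 2 * `approx_morph_size` expanded bases are emitted. Because
#' each variant site is decided independently by coverage, the walk can pair
#' alleles that never co-occur in a single repeat unit — a mosaic that
#' exists in no genomic copy.
#'
#' @param graph an `allele_graph`.
#' @param anchor anchor node id (must lie on a cycle).
#' @param approx_morph_size approximate repeat-unit size in bp.
#' @return consensus sequence string.
#' @export
genome_wide_consensus <- function(graph, anchor, approx_morph_size) {
  al <- if (inherits(graph, "graph_aligner")) graph else
    graph_aligner(graph, build_index = FALSE)
  start <- oi_of(anchor, "+")
  ois <- start
  total <- al$exp_oi[start]
  closed <- FALSE
  repeat {
    cur <- ois[length(ois)]
    nbs <- al$adj_to[[cur]] # pre-sorted: coverage desc, then lowest target
    if (length(nbs) == 0) {
      stop("consensus walk dead-ends: graph is not cyclic at the anchor node")
    }
    nxt <- nbs[1]
    ois <- c(ois, nxt)
    if (nxt == start) { closed <- TRUE; break }
    total <- total + al$eff_oi[nxt]
    if (total >= 2 * approx_morph_size) break
  }
  pe <- path_expand_oi(al, ois)
  if (closed) {
    # one full traversal, anchor start back to anchor start
    substr(pe$seq, 1, pe$offsets[length(ois)])
  } else {
    pe$seq
  }
}
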