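#' Rotation-aware morph matching
#'
#' Two morphs match when they align at >= 99% identity covering >= 99% of
#' both. Repeat units have arbitrary origins, so `b` (and its reverse
#' complement) is compared against rotations of `a`: candidate rotation
#' offsets come from exact 21-mer probes of `b` located in `a` doubled, the
#' best global alignment is kept, and terminal gaps are trimmed before
#' computing identity and the per-sequence aligned fractions.
#'
#' @param a,b morph sequences (non-empty strings).
#' @param trace keep the alignment operations of the best candidate (needed
#'   by [classify_errors()]).
#' @return a `match_result`: `identity`, `cov_a`, `cov_b`, `is_match`,
#'   `edits`, plus `strand`/`offset` of the best rotation and (with
#'   `trace = TRUE`) `ops` and the rotated `a`.
#' @export
match_morphs <- function(a, b, trace = FALSE) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  a <- toupper(a); b <- toupper(b)
  la <- nchar(a); lb <- nchar(b)
  a2 <- paste0(a, a)
  best <- list(d = Inf, offset = 0L, strand = "+")
  for (strand in c("+", "-")) {
    bs <- if (strand == "-") cpp_revcomp(b) else b
    offs <- rotation_candidates(a2, la, bs)
    for (off in offs) {
      ar <- paste0(substr(a2, off + 1, off + la))
      d <- cpp_edit_distance(bs, ar, -1)
      if (d < best$d) best <- list(d = d, offset = off, strand = strand, ar = ar,
                                   bs = bs)
    }
  }
  d <- best$d
  maxlen <- max(la, lb)
  close_enough <- d / maxlen <= 0.05
  if (close_enough || trace) {
    aln <- cpp_align_global(best$ar, best$bs, band = as.integer(d + 16))
    ops <- strsplit(aln$ops, "", fixed = TRUE)[[1]]
    # trim terminal gap runs (unaligned overhangs)
    n_ops <- length(ops)
    lead <- 0L
    while (lead < n_ops && ops[lead + 1L] %in% c("D", "I")) lead <- lead + 1L
    trail <- 0L
    while (trail < n_ops - lead && ops[n_ops - trail] %in% c("D", "I")) {
      trail <- trail + 1L
    }
    core <- if (n_ops - lead - trail > 0) ops[(lead + 1L):(n_ops - trail)] else
      character(0)
    core_edits <- sum(core != "M")
    core_len <- length(core)
    identity <- if (core_len > 0) 1 - core_edits / core_len else 0
    term <- c(ops[seq_len(lead)], if (trail) ops[seq.int(n_ops - trail + 1L, n_ops)])
    cov_a <- 1 - sum(term == "D") / la
    cov_b <- 1 - sum(term == "I") / lb
    edits <- core_edits
  } else {
    identity <- 1 - d / maxlen
    cov_a <- 1; cov_b <- 1
    edits <- d
    ops <- NULL
  }
  res <- list(identity = identity, cov_a = cov_a, cov_b = cov_b,
              is_match = identity >= 0.99 && cov_a >= 0.99 && cov_b >= 0.99,
              edits = edits, strand = best$strand, offset = best$offset)
  if (trace) {
    res$ops <- ops
    res$a_rot <- best$ar
    res$b_used <- best$bs
  }
  structure(res, class = "match_result")
}

# candidate rotation offsets of `a` (doubled as a2) from exact 21-mer probes
# taken along b; offset 0 is always included.
rotation_candidates <- function(a2, la, b) {
  lb <- nchar(b)
  probes <- unique(pmax(0L, pmin(lb - 21L, c(0L, floor(lb * c(0.25, 0.5, 0.75))))))
  offs <- 0L
  for (p in probes) {
    if (p < 0) next
    pat <- substr(b, p + 1, p + 21)
    if (nchar(pat) < 21) next
    hits <- gregexpr(pat, a2, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    cand <- (as.integer(hits) - 1L - p) %% la
    offs <- c(offs, cand)
  }
  offs <- unique(offs)
  if (length(offs) > 24) offs <- offs[seq_len(24)]
  offs
}

#' Classify alignment errors
#'
#' Each edited base of an alignment trace is labeled: a single-base indel
#' whose base extends an adjacent run of the same base (run >= 2) in either
#' sequence is a homopolymer indel; an indel that is an integer number of
#' copies of a 2-6 bp motif with at least one adjacent copy of that motif in
#' context is a microsatellite indel; substitutions and all remaining indels
#' are "other". Fractions are over total edited bases and sum to 1.
#'
#' @param match a `match_result` computed with `trace = TRUE`, or a list
#'   with elements `ops`, `a_rot`, `b_used`.
#' @return named numeric vector (homopolymer_indel, microsatellite_indel,
#'   other).
#' @export
classify_errors <- function(match) {
  ops <- match$ops
  a <- match$a_rot
  b <- match$b_used
  if (is.null(ops)) stop("classify_errors needs a trace; rerun match_morphs(trace = TRUE)")
  counts <- c(homopolymer_indel = 0, microsatellite_indel = 0, other = 0)
  i <- 0L; j <- 0L
  n <- length(ops)
  t <- 1L
  while (t <= n) {
    op <- ops[t]
    if (op == "M") { i <- i + 1L; j <- j + 1L; t <- t + 1L; next }
    if (op == "X") {
      counts["other"] <- counts["other"] + 1
      i <- i + 1L; j <- j + 1L; t <- t + 1L; next
    }
    # indel run (consecutive identical D or I ops)
    t2 <- t
    while (t2 < n && ops[t2 + 1L] == op) t2 <- t2 + 1L
    len <- t2 - t + 1L
    if (op == "D") {
      gap_seq <- substr(a, i + 1L, i + len)
      cls <- classify_indel(gap_seq, a, i, b, j)
      i <- i + len
    } else {
      gap_seq <- substr(b, j + 1L, j + len)
      cls <- classify_indel(gap_seq, b, j, a, i)
      j <- j + len
    }
    counts[cls] <- counts[cls] + len
    t <- t2 + 1L
  }
  tot <- sum(counts)
  if (tot == 0) return(counts)
  counts / tot
}

# gap_seq was inserted/deleted at position `pos` (0-based, gap sits between
# pos and pos+1) of `carrier` (the sequence that contains it); `other` /
# `opos` give the flanking context in the second sequence.
classify_indel <- function(gap_seq, carrier, pos, other, opos) {
  len <- nchar(gap_seq)
  first <- substr(gap_seq, 1, 1)
  if (len == 1L) {
    ctx <- c(substr(carrier, pos, pos), substr(carrier, pos + 2, pos + 2),
             substr(other, opos, opos), substr(other, opos + 1, opos + 1))
    if (first %in% ctx) return("homopolymer_indel")
  }
  for (p in 2:6) {
    if (p > len || len %% p != 0L) next
    motif <- substr(gap_seq, 1, p)
    if (strrep(motif, len / p) != gap_seq) next
    before_c <- substr(carrier, pos - p + 1, pos)
    after_c <- substr(carrier, pos + len + 1, pos + len + p)
    before_o <- substr(other, opos - p + 1, opos)
    after_o <- substr(other, opos + 1, opos + p)
    if (motif %in% c(before_c, after_c, before_o, after_o)) {
      return("microsatellite_indel")
    }
  }
  "other"
}

#' Score predicted morphs against ground truth
#'
#' Sensitivity is the fraction of qualifying truth morphs matched by at
#' least one prediction; specificity is the fraction of qualifying
#' predictions matching at least one truth morph (precision over
#' predictions). A truth morph qualifies when its copy count is at least
#' `min_truth_copies` or its best-matching prediction has coverage at least
#' `min_pred_coverage`; a prediction qualifies when its coverage is at least
#' `min_pred_coverage` or its best-matching truth morph has copy count at
#' least `min_truth_copies` (with both minima at 1 nothing is filtered).
#' Matching is many-to-many under the 99%/99% criterion of
#' [match_morphs()]; the best match per truth morph (highest identity, ties
#' to highest coverage) feeds the coverage/copy-count Pearson correlation
#' and the mean mismatch count.
#'
#' @param truth list of morphs with `sequence` and `copy_count` (as from
#'   [generate_morphs()]).
#' @param predicted list of morphs with `sequence` and `coverage`.
#' @param min_truth_copies,min_pred_coverage abundance filters (1 = none).
#' @return an `eval_report`: `sensitivity`, `specificity`, `pearson_r`,
#'   `mean_mismatches`, `error_fractions`, `matches` (data.frame), counts.
#' @export
score_assembly <- function(truth, predicted, min_truth_copies = 1,
                           min_pred_coverage = 1) {
  nt <- length(truth); np <- length(predicted)
  if (nt == 0) stop("empty truth set")
  t_copy <- vapply(truth, function(m) as.numeric(m$copy_count %||% 1), numeric(1))
  p_cov <- vapply(predicted, function(m) as.numeric(m$coverage %||% 1), numeric(1))
  rows <- list()
  best_for_truth <- rep(NA_integer_, nt)
  best_ident <- rep(-Inf, nt)
  matched_t <- rep(FALSE, nt)
  matched_p <- rep(FALSE, np)
  for (it in seq_len(nt)) {
    for (ip in seq_len(np)) {
      mr <- match_morphs(truth[[it]]$sequence, predicted[[ip]]$sequence)
      if (mr$is_match) {
        matched_t[it] <- TRUE; matched_p[ip] <- TRUE
        rows[[length(rows) + 1L]] <-
          data.frame(truth_id = truth[[it]]$morph_id %||% it,
                     pred_id = predicted[[ip]]$morph_id %||% ip,
                     identity = mr$identity, cov_a = mr$cov_a, cov_b = mr$cov_b,
                     edits = mr$edits, truth_copies = t_copy[it],
                     pred_coverage = p_cov[ip], stringsAsFactors = FALSE)
        better <- mr$identity > best_ident[it] ||
          (mr$identity == best_ident[it] && !is.na(best_for_truth[it]) &&
             p_cov[ip] > p_cov[best_for_truth[it]])
        if (is.na(best_for_truth[it]) || better) {
          best_for_truth[it] <- ip; best_ident[it] <- mr$identity
        }
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(truth_id = character(), pred_id = character(),
               identity = numeric(), cov_a = numeric(), cov_b = numeric(),
               edits = numeric(), truth_copies = numeric(),
               pred_coverage = numeric(), stringsAsFactors = FALSE)
  # abundance qualification (OR rule; minima of 1 disable filtering)
  best_cov <- ifelse(is.na(best_for_truth), -Inf, p_cov[best_for_truth])
  q_truth <- t_copy >= min_truth_copies | (matched_t & best_cov >= min_pred_coverage)
  best_copy_for_pred <- vapply(seq_len(np), function(ip) {
    hit <- matches$truth_copies[matches$pred_id == (predicted[[ip]]$morph_id %||% ip)]
    if (length(hit)) max(hit) else -Inf
  }, numeric(1))
  q_pred <- p_cov >= min_pred_coverage |
    (matched_p & best_copy_for_pred >= min_truth_copies)
  sensitivity <- if (sum(q_truth)) mean(matched_t[q_truth]) else NA_real_
  specificity <- if (np == 0 || sum(q_pred) == 0) NA_real_ else
    mean(matched_p[q_pred])
  pairs <- which(matched_t)
  pearson_r <- if (length(pairs) >= 3) {
    x <- t_copy[pairs]; y <- p_cov[best_for_truth[pairs]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  } else NA_real_
  mean_mismatches <- if (length(pairs)) {
    mean(vapply(pairs, function(it) {
      min(matches$edits[matches$truth_id == (truth[[it]]$morph_id %||% it)])
    }, numeric(1)))
  } else NA_real_
  ef <- if (length(pairs)) {
    agg <- c(homopolymer_indel = 0, microsatellite_indel = 0, other = 0)
    tot_edits <- 0
    for (it in pairs) {
      mr <- match_morphs(truth[[it]]$sequence,
                         predicted[[best_for_truth[it]]]$sequence, trace = TRUE)
      if (mr$edits > 0) {
        agg <- agg + classify_errors(mr) * mr$edits
        tot_edits <- tot_edits + mr$edits
      }
    }
    if (tot_edits > 0) agg / tot_edits else
      c(homopolymer_indel = 0, microsatellite_indel = 0, other = 0)
  } else c(homopolymer_indel = NA_real_, microsatellite_indel = NA_real_,
           other = NA_real_)
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 pearson_r = pearson_r, mean_mismatches = mean_mismatches,
                 error_fractions = ef, matches = matches,
                 n_truth = nt, n_predicted = np,
                 n_truth_qualified = sum(q_truth),
                 n_pred_qualified = if (np) sum(q_pred) else 0L),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("eval_report: sensitivity %.3f (%d truth), ",
                     "specificity %s (%d predictions), r %s\n"),
              x$sensitivity, x$n_truth_qualified,
              ifelse(is.na(x$specificity), "NA", sprintf("%.3f", x$specificity)),
              x$n_pred_qualified,
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r))))
  invisible(x)
}
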