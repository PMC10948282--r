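# Shared fixtures and independent oracles.

rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

# mutate a sequence with n_sub substitutions at distinct positions
mutate_subs <- function(seq, n_sub) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- sample(length(v), n_sub)
  for (p in idx) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# independent DP edit distance (base R)
dp_ed <- function(a, b) as.integer(adist(a, b))

# brute-force canonical k-mer multiset of sequences
brute_canon_kmers <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      r <- paste(revcomp(w))
      out <- c(out, if (w <= r) w else r)
    }
  }
  out
}

# error-free tiling reads over a sequence
tiling_reads <- function(target, read_len, step) {
  starts <- seq(1, max(1, nchar(target) - read_len), by = step)
  data.frame(id = sprintf("r%04d", seq_along(starts)), desc = "",
             seq = vapply(starts, function(s)
               substr(target, s, s + read_len - 1), character(1)),
             stringsAsFactors = FALSE)
}

# memoized single-morph tandem fixture: one 2 kb unit, 10 copies,
# error-free accurate reads, cleaned graph and aligner
.fixture_env <- new.env(parent = emptyenv())
single_morph_fixture <- function() {
  if (!is.null(.fixture_env$single)) return(.fixture_env$single)
  set.seed(424242)
  morph <- rseq(2000)
  array <- strrep(morph, 10)
  reads <- tiling_reads(array, 4000, 400)
  graph <- clean_graph(build_allele_graph(reads, k = 31, solid_min = 2),
                       min_node_coverage = 2)
  aligner <- graph_aligner(graph, 17)
  fx <- list(morph = morph, array = array, reads = reads, graph = graph,
             aligner = aligner, anchor = select_anchor_node(graph))
  .fixture_env$single <- fx
  fx
}

# scikit-learn DBSCAN over a batch of precomputed-distance instances;
# each instance: list(D = matrix (NA = far), eps, min_pts).
# Returns per instance: list(labels (0-based cluster ids, -1 noise),
# core (1-based indices of core points)).
sklearn_dbscan_batch <- function(instances) {
  tf <- tempfile(fileext = ".json")
  of <- tempfile(fileext = ".json")
  payload <- lapply(instances, function(it) {
    D <- it$D
    D[is.na(D)] <- 1e9
    list(D = unname(as.matrix(D)), eps = it$eps, min_pts = it$min_pts)
  })
  jsonlite::write_json(payload, tf, digits = NA)
  py <- paste(
    "import json, sys",
    "import numpy as np",
    "from sklearn.cluster import DBSCAN",
    "data = json.load(open(sys.argv[1]))",
    "out = []",
    "for it in data:",
    "    D = np.array(it['D'], dtype=float)",
    "    m = DBSCAN(eps=it['eps'][0], min_samples=it['min_pts'][0],",
    "               metric='precomputed').fit(D)",
    "    out.append({'labels': [int(x) for x in m.labels_],",
    "                'core': [int(x) + 1 for x in m.core_sample_indices_]})",
    "json.dump(out, open(sys.argv[2], 'w'))",
    sep = "\n")
  status <- system2("python", c("-c", shQuote(py), tf, of))
  stopifnot(status == 0)
  jsonlite::read_json(of, simplifyVector = FALSE)
}
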