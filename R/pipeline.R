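#' Pipeline configuration
#'
#' Collects every tunable of the reference-based workflow. The defaults
#' target a human-scale rDNA locus (~45 kb units); the HiFi-only mode for
#' short units overrides `max_rough_diff` to 10 edits and `min_epsilon` to 1
#' and clusters with `min_pts = 2`.
#'
#' @param reference reference repeat sequence: FASTA path or record
#'   data.frame.
#' @param hifi accurate long reads: FASTA/FASTQ path(s) or record data.frame.
#' @param ont ultralong noisy reads (optional in hifi-only mode).
#' @param out_dir output directory (created if missing).
#' @param approx_morph_size approximate repeat-unit size in bp (default
#'   45000).
#' @param k_graph de Bruijn k in homopolymer-compressed space.
#' @param k_recruit recruitment k-mer size.
#' @param anchor_k anchor seed length for graph alignment.
#' @param solid_min solid k-mer threshold (or `"auto"`).
#' @param min_fraction_hifi,min_fraction_ont recruitment thresholds.
#' @param max_rough_diff union-find join threshold in edits (default 1% of
#'   `approx_morph_size`).
#' @param min_epsilon DBSCAN epsilon floor in edits.
#' @param min_pts DBSCAN core-point threshold.
#' @param min_node_coverage,max_tip_length graph cleaning thresholds.
#' @param report_min_coverage morphs below this loop coverage are flagged
#'   low-confidence (reporting only; never a clustering filter).
#' @param min_identity alignment identity floor for emitted read paths.
#' @param seed RNG seed (the core pipeline is deterministic; the seed is
#'   recorded for provenance).
#' @param mode `"ref"` or `"hifi-only"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(reference, hifi, ont = NULL, out_dir = tempfile("ribomorph_"),
                            approx_morph_size = 45000, k_graph = 101,
                            k_recruit = 21, anchor_k = 17, solid_min = 5,
                            min_fraction_hifi = 0.2, min_fraction_ont = 0.1,
                            max_rough_diff = NULL, min_epsilon = 1,
                            min_pts = NULL, min_node_coverage = NULL,
                            max_tip_length = NULL, report_min_coverage = 30,
                            min_identity = 0.75, seed = 1,
                            mode = c("ref", "hifi-only")) {
  mode <- match.arg(mode)
  if (mode == "hifi-only") {
    if (is.null(max_rough_diff)) max_rough_diff <- 10
    if (is.null(min_pts)) min_pts <- 2
    if (is.null(ont)) ont <- hifi
  } else {
    # the rough threshold must comfortably exceed the within-morph loop
    # divergence of the seed-and-chain aligner (a few percent), or true
    # clusters fragment before DBSCAN ever runs
    if (is.null(max_rough_diff)) max_rough_diff <- round(0.04 * approx_morph_size)
    if (is.null(min_pts)) min_pts <- 5
    if (is.null(ont)) stop("ont reads are required in ref mode")
  }
  if (approx_morph_size <= 2 * k_graph) {
    stop("approx_morph_size must exceed 2 * k_graph")
  }
  structure(list(reference = reference, hifi = hifi, ont = ont,
                 out_dir = out_dir, approx_morph_size = approx_morph_size,
                 k_graph = as.integer(k_graph), k_recruit = as.integer(k_recruit),
                 anchor_k = as.integer(anchor_k), solid_min = solid_min,
                 min_fraction_hifi = min_fraction_hifi,
                 min_fraction_ont = min_fraction_ont,
                 max_rough_diff = max_rough_diff,
                 min_epsilon = min_epsilon, min_pts = as.integer(min_pts),
                 min_node_coverage = min_node_coverage,
                 max_tip_length = max_tip_length,
                 report_min_coverage = report_min_coverage,
                 min_identity = min_identity,
                 seed = as.integer(seed), mode = mode),
            class = "pipeline_config")
}

as_records <- function(x, what) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && all(file.exists(x))) {
    recs <- lapply(x, read_sequences)
    return(do.call(rbind, recs))
  }
  if (is.character(x)) { # bare sequences
    out <- data.frame(id = sprintf("%s_%d", what, seq_along(x)),
                      desc = "", seq = toupper(x), stringsAsFactors = FALSE)
    out$qual <- vector("list", nrow(out))
    return(out)
  }
  stop("cannot interpret ", what, " input")
}

#' Run the reference-based morph assembly pipeline
#'
#' Executes the full workflow: k-mer recruitment of accurate reads against
#' the reference, allele-graph construction and cleaning, recruitment of
#' ultralong reads against the graph's k-mers, sequence-to-graph alignment,
#' loop extraction, pairwise-distance clustering (union-find rough clusters,
#' data-driven epsilon, DBSCAN), per-cluster consensus polishing and the
#' genome-wide consensus walk. All intermediate artifacts, a run log and a
#' machine-readable manifest are written to `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `morphs`, `consensus`, `graph`, `loops`,
#'   `clusters`, `epsilon`, `report` paths and stage counts.
#' @export
run_ref_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  stage_t0 <- Sys.time()
  log_add <- function(...) {
    line <- sprintf(...)
    message(sprintf("[%6.1fs] %s", as.numeric(Sys.time() - stage_t0, units = "secs"),
                    line))
    log_lines <<- c(log_lines, line)
  }
  log_add("ribomorph %s mode; seed=%d", cfg$mode, cfg$seed)
  log_add("params: approx_morph_size=%d k_graph=%d k_recruit=%d anchor_k=%d",
          cfg$approx_morph_size, cfg$k_graph, cfg$k_recruit, cfg$anchor_k)
  log_add("params: max_rough_diff=%g min_epsilon=%g min_pts=%d report_min_coverage=%g",
          cfg$max_rough_diff, cfg$min_epsilon, cfg$min_pts, cfg$report_min_coverage)

  reference <- as_records(cfg$reference, "reference")
  hifi <- as_records(cfg$hifi, "hifi")
  ont <- as_records(cfg$ont, "ont")
  if (cfg$mode == "hifi-only") {
    med_len <- stats::median(nchar(hifi$seq))
    if (cfg$approx_morph_size > med_len) {
      warning("morph size exceeds typical read length; HiFi-only mode needs ",
              "reads spanning complete units")
    }
  }
  log_add("input: %d reference records, %d accurate reads, %d ultralong reads",
          nrow(reference), nrow(hifi), nrow(ont))

  # stage 1: recruit accurate reads against the reference
  ref_index <- build_kmer_index(reference, cfg$k_recruit)
  rec_hifi <- recruit_reads(hifi, ref_index, cfg$min_fraction_hifi)
  write_tsv_report(rec_hifi$decisions, file.path(cfg$out_dir, "recruit_hifi.tsv"))
  log_add("recruit: %d/%d accurate reads recruited", nrow(rec_hifi$reads), nrow(hifi))
  if (nrow(rec_hifi$reads) == 0) {
    stage_stop("recruit", "no accurate reads recruited",
               "is the reference related closely enough to the sample rDNA?")
  }

  # stage 2: allele graph
  graph <- build_allele_graph(rec_hifi$reads, k = cfg$k_graph,
                              solid_min = cfg$solid_min)
  graph <- clean_graph(graph,
                       min_node_coverage = cfg$min_node_coverage %||%
                         max(2, if (is.numeric(cfg$solid_min)) cfg$solid_min else 2),
                       max_tip_length = cfg$max_tip_length %||% (2 * cfg$k_graph))
  write_gfa(graph, file.path(cfg$out_dir, "allele_graph.gfa"))
  write_tsv_report(data.frame(id = graph$nodes$id, length = graph$nodes$len,
                              coverage = graph$nodes$cov),
                   file.path(cfg$out_dir, "nodes.tsv"))
  log_add("allele_graph: %d nodes, %d edges", nrow(graph$nodes), nrow(graph$edges))

  # stage 3: recruit ultralong reads against the graph k-mers
  al <- graph_aligner(graph, cfg$anchor_k)
  node_index <- build_kmer_index(al$node_exp, cfg$k_recruit)
  rec_ont <- recruit_reads(ont, node_index, cfg$min_fraction_ont)
  write_tsv_report(rec_ont$decisions, file.path(cfg$out_dir, "recruit_ont.tsv"))
  log_add("recruit: %d/%d ultralong reads recruited", nrow(rec_ont$reads), nrow(ont))
  if (nrow(rec_ont$reads) == 0) {
    stage_stop("recruit", "no ultralong reads recruited",
               "check the allele graph and min_fraction_ont")
  }

  # stage 4: align ultralong reads to the graph
  paths <- list()
  for (i in seq_len(nrow(rec_ont$reads))) {
    ap <- align_read(rec_ont$reads[i, , drop = FALSE], al,
                     min_identity = cfg$min_identity)
    paths <- c(paths, ap)
  }
  aln_df <- do.call(rbind, lapply(paths, function(p) {
    data.frame(read_id = p$read_id,
               path = paste(paste0(p$path$id, p$path$o), collapse = ","),
               read_start = p$read_interval[1], read_end = p$read_interval[2],
               identity = p$identity, stringsAsFactors = FALSE)
  }))
  if (is.null(aln_df)) aln_df <- data.frame(read_id = character(),
                                            path = character(),
                                            read_start = integer(),
                                            read_end = integer(),
                                            identity = numeric())
  write_tsv_report(aln_df, file.path(cfg$out_dir, "alignments.tsv"))
  log_add("graph_align: %d alignment paths from %d reads",
          length(paths), nrow(rec_ont$reads))

  # stage 5: loops
  anchor <- select_anchor_node(graph)
  log_add("loops: anchor node %d (len %d, cov %.1f)", anchor,
          graph$nodes$len[match(anchor, graph$nodes$id)],
          graph$nodes$cov[match(anchor, graph$nodes$id)])
  loops <- list(); discarded <- 0L
  for (p in paths) {
    lp <- extract_loops(p, anchor, cfg$approx_morph_size, al)
    discarded <- discarded + attr(lp, "discarded")
    loops <- c(loops, lp)
  }
  log_add("loops: %d extracted, %d discarded by length filter",
          length(loops), discarded)
  if (length(loops) == 0) {
    stage_stop("loops", "no loops extracted",
               "are the ultralong reads long enough to span complete units?")
  }
  loop_ids <- vapply(loops, function(l) paste0(l$read_id, "_", l$ordinal),
                     character(1))
  write_fasta(data.frame(id = loop_ids, desc = "",
                         seq = vapply(loops, `[[`, character(1), "sequence"),
                         stringsAsFactors = FALSE),
              file.path(cfg$out_dir, "loops.fasta"), sort = FALSE)

  # stage 6: cluster
  D <- pairwise_distances(loops, limit = cfg$max_rough_diff)
  rough <- rough_cluster(D, cfg$max_rough_diff)
  eps <- estimate_epsilon(rough, D, cfg$min_epsilon)
  db <- dbscan_cluster(loops, D, eps, cfg$min_pts)
  log_add("cluster: %d rough clusters, epsilon=%g, %d density clusters, %d noise",
          length(rough), eps, length(db$clusters), length(db$noise))
  rough_of <- integer(length(loops))
  for (i in seq_along(rough)) rough_of[rough[[i]]] <- i
  dens_of <- rep(NA_integer_, length(loops))
  for (i in seq_along(db$clusters)) dens_of[db$clusters[[i]]] <- i
  write_tsv_report(data.frame(loop_id = loop_ids, rough_cluster = rough_of,
                              morph_cluster = ifelse(is.na(dens_of), "noise",
                                                     dens_of)),
                   file.path(cfg$out_dir, "clusters.tsv"))
  jsonlite::write_json(list(epsilon = eps, min_pts = cfg$min_pts,
                            max_rough_diff = cfg$max_rough_diff),
                       file.path(cfg$out_dir, "params.json"), auto_unbox = TRUE)
  if (length(db$clusters) == 0) {
    stage_stop("cluster", "DBSCAN produced no clusters",
               "lower min_pts or check loop coverage")
  }

  # stage 7: consensus per cluster
  loop_seqs <- vapply(loops, `[[`, character(1), "sequence")
  morphs <- lapply(seq_along(db$clusters), function(i) {
    cl <- db$clusters[[i]]
    med <- medoid(cl, loops, D)
    cons <- polish(loop_seqs[med], loop_seqs[cl])
    # final unbiased polish against the raw read segments of the same loops:
    # graph-threaded loops share the graph's collapsed homopolymer /
    # microsatellite run estimates, so a majority over the (noisy but
    # unbiased) read-space sequences restores morph-specific run lengths
    rseqs <- unlist(lapply(loops[cl], function(l)
      l$read_sequence %||% character(0)))
    if (length(rseqs) >= 3) cons <- polish(cons, rseqs, max_rounds = 3)
    list(morph_id = NA_character_, sequence = cons, coverage = length(cl),
         cluster_ref = i, length = nchar(cons))
  })
  ord <- order(-vapply(morphs, `[[`, numeric(1), "coverage"),
               vapply(morphs, `[[`, numeric(1), "cluster_ref"))
  morphs <- morphs[ord]
  for (i in seq_along(morphs)) morphs[[i]]$morph_id <- sprintf("morph_%d", i)
  low <- vapply(morphs, function(m) m$coverage < cfg$report_min_coverage,
                logical(1))
  log_add("consensus: %d morphs (%d below coverage %g flagged low-confidence)",
          length(morphs), sum(low), cfg$report_min_coverage)
  write_fasta(data.frame(
    id = vapply(morphs, `[[`, character(1), "morph_id"),
    desc = vapply(morphs, function(m)
      sprintf("coverage=%d length=%d%s", m$coverage, m$length,
              if (m$coverage < cfg$report_min_coverage) " low_confidence" else ""),
      character(1)),
    seq = vapply(morphs, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE),
    file.path(cfg$out_dir, "morphs.fasta"), sort = FALSE)
  write_tsv_report(data.frame(
    morph_id = vapply(morphs, `[[`, character(1), "morph_id"),
    coverage = vapply(morphs, `[[`, numeric(1), "coverage"),
    length = vapply(morphs, `[[`, numeric(1), "length")),
    file.path(cfg$out_dir, "summary.tsv"))

  # stage 8: genome-wide consensus
  consensus <- tryCatch(
    genome_wide_consensus(graph, anchor, cfg$approx_morph_size),
    error = function(e) { log_add("consensus walk failed: %s",
                                  conditionMessage(e)); NA_character_ })
  if (!is.na(consensus)) {
    write_fasta(data.frame(id = "genome_wide_consensus", desc = "",
                           seq = consensus, stringsAsFactors = FALSE),
                file.path(cfg$out_dir, "consensus.fasta"))
  }

  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  outputs <- c("recruit_hifi.tsv", "allele_graph.gfa", "nodes.tsv",
               "recruit_ont.tsv", "alignments.tsv", "loops.fasta",
               "clusters.tsv", "params.json", "morphs.fasta", "summary.tsv",
               if (!is.na(consensus)) "consensus.fasta", "run.log")
  manifest <- list(
    mode = cfg$mode, seed = cfg$seed,
    parameters = cfg[c("approx_morph_size", "k_graph", "k_recruit", "anchor_k",
                       "min_fraction_hifi", "min_fraction_ont",
                       "max_rough_diff", "min_epsilon", "min_pts",
                       "report_min_coverage", "min_identity")],
    epsilon = eps,
    counts = list(hifi_recruited = nrow(rec_hifi$reads),
                  ont_recruited = nrow(rec_ont$reads),
                  alignment_paths = length(paths),
                  loops = length(loops), loops_discarded = discarded,
                  rough_clusters = length(rough),
                  morph_clusters = length(db$clusters),
                  noise_loops = length(db$noise),
                  morphs = length(morphs)),
    files = lapply(stats::setNames(outputs, outputs), function(f)
      unname(tools::md5sum(file.path(cfg$out_dir, f)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(morphs = morphs, consensus = consensus, graph = graph,
                 loops = loops, loop_ids = loop_ids, distances = D,
                 rough = rough, clusters = db, epsilon = eps,
                 anchor = anchor, paths = paths, out_dir = cfg$out_dir))
}

#' Run the HiFi-only short-morph mode
#'
#' For genomes whose repeat units are shorter than accurate reads, the same
#' pipeline runs with the accurate reads in both roles and tight clustering
#' parameters (`max_rough_diff = 10`, `min_epsilon = 1`, `min_pts = 2`).
#'
#' @param config a [pipeline_config()]; its mode is forced to `"hifi-only"`.
#' @return as [run_ref_pipeline()].
#' @export
run_hifi_only <- function(config) {
  cfg <- config
  if (cfg$mode != "hifi-only") {
    cfg <- pipeline_config(reference = cfg$reference, hifi = cfg$hifi,
                           ont = cfg$hifi, out_dir = cfg$out_dir,
                           approx_morph_size = cfg$approx_morph_size,
                           k_graph = cfg$k_graph, k_recruit = cfg$k_recruit,
                           anchor_k = cfg$anchor_k, solid_min = cfg$solid_min,
                           min_fraction_hifi = cfg$min_fraction_hifi,
                           min_fraction_ont = cfg$min_fraction_ont,
                           report_min_coverage = cfg$report_min_coverage,
                           min_identity = cfg$min_identity,
                           seed = cfg$seed, mode = "hifi-only")
  }
  run_ref_pipeline(cfg)
}
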