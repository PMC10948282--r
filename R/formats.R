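#' Read sequences from FASTA or FASTQ
#'
#' Strict reader for the two read formats the pipeline consumes. Lowercase
#' bases are uppercased, U is mapped to T, and any character outside
#' A/C/G/T/N raises a parse error naming the offending line. FASTQ records
#' must use the 4-line dialect with Phred+33 qualities. Gzipped files are
#' handled transparently.
#'
#' @param path file path (optionally `.gz`).
#' @param format one of `"fasta"`, `"fastq"`, `"auto"`. With `"auto"` the
#'   format is sniffed from the first non-empty character (`>` vs `@`).
#' @return a data.frame with columns `id`, `desc`, `seq` and a list-column
#'   `qual` (integer Phred scores, or `NULL` for FASTA records).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) {
    return(data.frame(id = character(), desc = character(),
                      seq = character(), stringsAsFactors = FALSE) |>
             (\(d) { d$qual <- list(); d })())
  }
  if (format == "auto") {
    first <- substr(trimws(lines[nonempty[1]]), 1, 1)
    format <- switch(first, ">" = "fasta", "@" = "fastq",
                     stop("cannot sniff format: first record starts with '",
                          first, "' (line ", nonempty[1], ")"))
  }
  if (format == "fasta") parse_fasta(lines) else parse_fastq(lines)
}

clean_bases <- function(seq, line_no) {
  s <- toupper(seq)
  s <- chartr("U", "T", s)
  bad <- regmatches(s, regexpr("[^ACGTN]", s))
  if (length(bad) && nzchar(bad)) {
    stop("invalid base character '", bad, "' at line ", line_no)
  }
  s
}

parse_fasta <- function(lines) {
  hdr <- grepl("^>", lines)
  if (any(nzchar(trimws(lines)) & !hdr & cumsum(hdr) == 0)) {
    stop("sequence data before first header at line ",
         which(nzchar(trimws(lines)) & cumsum(hdr) == 0)[1])
  }
  idx <- which(hdr)
  ids <- character(length(idx)); descs <- character(length(idx))
  seqs <- character(length(idx))
  bounds <- c(idx, length(lines) + 1L)
  for (i in seq_along(idx)) {
    h <- sub("^>", "", lines[idx[i]])
    toks <- strsplit(trimws(h), "[ \t]+")[[1]]
    if (length(toks) == 0 || !nzchar(toks[1])) {
      stop("empty sequence id at line ", idx[i])
    }
    ids[i] <- toks[1]
    descs[i] <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
    body <- lines[seq.int(idx[i] + 1L, bounds[i + 1] - 1L)]
    body <- body[nzchar(trimws(body))]
    seqs[i] <- clean_bases(paste(gsub("[ \t]", "", body), collapse = ""), idx[i])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[anyDuplicated(ids)])
  }
  out <- data.frame(id = ids, desc = descs, seq = seqs,
                    stringsAsFactors = FALSE)
  out$qual <- vector("list", nrow(out))
  out
}

parse_fastq <- function(lines) {
  lines <- lines[nzchar(lines) | seq_along(lines) <= max(which(nzchar(lines)), 0)]
  # trailing blank lines tolerated; internal structure must be 4-line records
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ record near line ", length(lines))
  }
  n <- length(lines) / 4
  ids <- character(n); descs <- character(n); seqs <- character(n)
  quals <- vector("list", n)
  for (i in seq_len(n)) {
    l0 <- 4L * (i - 1L)
    h <- lines[l0 + 1L]
    if (!startsWith(h, "@")) stop("expected '@' header at line ", l0 + 1L)
    toks <- strsplit(trimws(sub("^@", "", h)), "[ \t]+")[[1]]
    if (length(toks) == 0 || !nzchar(toks[1])) {
      stop("empty sequence id at line ", l0 + 1L)
    }
    ids[i] <- toks[1]
    descs[i] <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
    seqs[i] <- clean_bases(lines[l0 + 2L], l0 + 2L)
    if (!startsWith(lines[l0 + 3L], "+")) {
      stop("expected '+' separator at line ", l0 + 3L)
    }
    q <- lines[l0 + 4L]
    if (nchar(q) != nchar(seqs[i])) {
      stop("quality length does not match sequence length at line ", l0 + 4L)
    }
    quals[[i]] <- as.integer(charToRaw(q)) - 33L
  }
  if (anyDuplicated(ids)) stop("duplicate sequence id: ", ids[anyDuplicated(ids)])
  out <- data.frame(id = ids, desc = descs, seq = seqs,
                    stringsAsFactors = FALSE)
  out$qual <- quals
  out
}

#' Write sequence records as FASTA
#'
#' Records are written sorted by id so output is byte-identical for equal
#' inputs.
#'
#' @param records data.frame with `id`, `seq` and optional `desc` columns.
#' @param path output path.
#' @param sort sort records by id before writing (default TRUE).
#' @export
write_fasta <- function(records, path, sort = TRUE) {
  if (nrow(records) && sort) records <- records[order(records$id), , drop = FALSE]
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  hdr <- paste0(">", records$id, ifelse(nzchar(desc), paste0(" ", desc), ""))
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(records)) {
    writeLines(as.vector(rbind(hdr, records$seq)), con, sep = "\n")
  }
  invisible(path)
}

#' Write sequence records as FASTQ (Phred+33)
#'
#' Records lacking qualities are written with a constant quality of 40.
#'
#' @inheritParams write_fasta
#' @export
write_fastq <- function(records, path, sort = TRUE) {
  if (nrow(records) && sort) records <- records[order(records$id), , drop = FALSE]
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    q <- records$qual[[i]]
    qs <- if (is.null(q)) {
      strrep(rawToChar(as.raw(40L + 33L)), nchar(records$seq[i]))
    } else {
      rawToChar(as.raw(q + 33L))
    }
    writeLines(c(paste0("@", records$id[i],
                        if (nzchar(desc[i])) paste0(" ", desc[i]) else ""),
                 records$seq[i], "+", qs), con, sep = "\n")
  }
  invisible(path)
}

#' Write an allele graph as GFA 1.0
#'
#' One S line per node carrying the run-length-expanded sequence and an
#' average-coverage `dp:f:` tag; one L line per edge with orientations and a
#' `(k-1)M` overlap CIGAR (overlap counted in homopolymer-compressed space).
#' The graph k is stored on the header as a `kc:i:` tag so that
#' [read_gfa()] can invert the writer.
#'
#' @param graph an [allele_graph] object.
#' @param path output path.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "allele_graph"))
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- sprintf("H\tVN:Z:1.0\tkc:i:%d", graph$k)
  nd <- graph$nodes
  if (nrow(nd)) {
    ord <- order(nd$id)
    lines <- c(lines, sprintf("S\t%d\t%s\tdp:f:%s", nd$id[ord],
                              vapply(nd$id[ord], function(i)
                                expand_node(graph, i), character(1)),
                              format(nd$cov[ord], trim = TRUE)))
  }
  ed <- graph$edges
  if (!is.null(ed) && nrow(ed)) {
    key <- order(ed$from, ed$from_o, ed$to, ed$to_o)
    ed <- ed[key, , drop = FALSE]
    lines <- c(lines, sprintf("L\t%d\t%s\t%d\t%s\t%dM\tec:f:%s",
                              ed$from, ed$from_o, ed$to, ed$to_o,
                              graph$k - 1L, format(ed$cov, trim = TRUE)))
  }
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a GFA 1.0 file written by [write_gfa()]
#'
#' S and L lines are parsed; unknown line types are ignored. An L line
#' referring to an absent segment is an error.
#'
#' @param path GFA file path.
#' @return an [allele_graph] object.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  k <- NA_integer_
  h <- grep("^H\t", lines, value = TRUE)
  if (length(h)) {
    m <- regmatches(h[1], regexpr("kc:i:[0-9]+", h[1]))
    if (length(m)) k <- as.integer(sub("kc:i:", "", m))
  }
  s_lines <- strsplit(grep("^S\t", lines, value = TRUE), "\t", fixed = TRUE)
  ids <- integer(0); seqs <- character(0); covs <- numeric(0)
  for (f in s_lines) {
    ids <- c(ids, as.integer(f[2]))
    seqs <- c(seqs, f[3])
    dp <- grep("^dp:f:", f, value = TRUE)
    covs <- c(covs, if (length(dp)) as.numeric(sub("dp:f:", "", dp[1])) else NA_real_)
  }
  l_lines <- strsplit(grep("^L\t", lines, value = TRUE), "\t", fixed = TRUE)
  ef <- integer(0); efo <- character(0); et <- integer(0); eto <- character(0)
  ecov <- numeric(0)
  for (f in l_lines) {
    a <- as.integer(f[2]); b <- as.integer(f[4])
    if (!(a %in% ids) || !(b %in% ids)) {
      stop("L line references absent segment: ", f[2], " -> ", f[4])
    }
    ef <- c(ef, a); efo <- c(efo, f[3]); et <- c(et, b); eto <- c(eto, f[5])
    ec <- grep("^ec:f:", f, value = TRUE)
    ecov <- c(ecov, if (length(ec)) as.numeric(sub("ec:f:", "", ec[1])) else NA_real_)
  }
  if (is.na(k)) {
    if (length(s_lines)) stop("GFA header lacks the kc:i tag written by write_gfa")
    k <- 0L
  }
  hp <- cpp_hpc_compress(seqs)
  nodes <- data.frame(id = ids, seq = unlist(hp$compressed) %||% character(0),
                      cov = covs, stringsAsFactors = FALSE)
  if (length(seqs) == 0) nodes <- data.frame(id = integer(), seq = character(),
                                             cov = numeric(), stringsAsFactors = FALSE)
  nodes$len <- nchar(seqs)
  g <- structure(list(
    k = k, nodes = nodes,
    runs = if (length(seqs)) hp$runs else list(),
    edges = data.frame(from = ef, from_o = efo, to = et, to_o = eto,
                       cov = ecov, stringsAsFactors = FALSE)),
    class = "allele_graph")
  g
}

#' Write a TSV report
#'
#' Tab-separated, header row, UTF-8, '.' decimal; deterministic output.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
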