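#' Simulation parameters for synthetic rDNA arrays
#'
#' The simulator builds a panel of source repeat units, generates morphs as
#' mosaics of the sources with additional random mutations, arranges copies
#' in a tandem array, and simulates platform-like reads. Defaults follow the
#' human rDNA setting: units of roughly 45 kb, morph panels whose average
#' pairwise divergence is 4.4%, of which 4.2% comes from mosaic sampling of
#' the sources and 0.2% from random mutations.
#'
#' @param n_sources number of source units in the panel (>= 2).
#' @param morph_length unit length in bp (>= 200).
#' @param n_morphs number of distinct morphs to generate.
#' @param mosaic_divergence target average pairwise divergence contributed by
#'   mosaic sampling of the source panel.
#' @param mutation_rate per-base rate of additional random mutations applied
#'   to each morph (80% substitutions, 20% single-base indels).
#' @param copy_count_law distribution of per-morph copy counts: a list with
#'   `type = "geometric"`, success probability `p`, and truncation bounds
#'   `min`/`max`, or `type = "fixed"` with `value`.
#' @param conserved_frac fraction of the unit kept nearly invariant across
#'   sources, mimicking the conserved rRNA coding core (divergence is
#'   concentrated in the remaining, IGS-like part so the average still meets
#'   `mosaic_divergence`).
#' @param seed integer RNG seed; every downstream draw derives from it.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_sources = 9, morph_length = 45000, n_morphs = 9,
                       mosaic_divergence = 0.042, mutation_rate = 0.002,
                       copy_count_law = list(type = "geometric", p = 0.25,
                                             min = 1, max = 15),
                       conserved_frac = 0.2, seed = 1) {
  stopifnot(n_sources >= 2, morph_length >= 200,
            mosaic_divergence >= 0, mosaic_divergence < 1,
            mutation_rate >= 0, mutation_rate < 1,
            conserved_frac >= 0, conserved_frac < 1)
  structure(list(n_sources = as.integer(n_sources),
                 morph_length = as.integer(morph_length),
                 n_morphs = as.integer(n_morphs),
                 mosaic_divergence = mosaic_divergence,
                 mutation_rate = mutation_rate,
                 copy_count_law = copy_count_law,
                 conserved_frac = conserved_frac,
                 seed = as.integer(seed)),
            class = "sim_params")
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# apply point mutations / short indels to a sequence at per-site rate `rate`;
# p_sub of events are substitutions, the rest indels of length drawn from
# `indel_len` (insertion or deletion with equal probability).
mutate_bases <- function(seq, rate, p_sub = 0.8, indel_len = function() 1L) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit) == 0) return(seq)
  ins <- character(length(v))
  del <- rep(FALSE, length(v))
  for (p in hit) {
    if (stats::runif(1) < p_sub) {
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    } else if (stats::runif(1) < 0.5) {
      ins[p] <- random_bases(indel_len())
    } else {
      l <- indel_len()
      del[p:min(length(v), p + l - 1L)] <- TRUE
    }
  }
  keep <- !del
  paste0(paste0(ins[keep], v[keep], collapse = ""), collapse = "")
}

#' Generate a panel of source repeat units
#'
#' Sources descend from a common random ancestor carrying an embedded tandem
#' motif region; per-source mutation concentrates in the IGS-like part of
#' the unit and includes SNPs, short (1-10 bp) indels and motif copy-number
#' changes. The per-source rate is calibrated so that the measured average
#' pairwise divergence (edit distance / mean length) is within 20% of
#' `mosaic_divergence`.
#'
#' @param params a [sim_params()] object.
#' @return character vector of `n_sources` sequences.
#' @export
generate_source_panel <- function(params) {
  if (params$mosaic_divergence > 0.3) {
    stop("unreachable divergence target: mosaic_divergence > 0.3")
  }
  set.seed(params$seed)
  L <- params$morph_length
  ancestor <- random_bases(L)
  # embedded tandem motif region (microsatellite) in the divergent part
  motif <- random_bases(sample(3:6, 1))
  n_copies <- sample(10:20, 1)
  ms_start <- max(1L, floor(L * (params$conserved_frac + 0.3)))
  ms <- strrep(motif, n_copies)
  ancestor <- paste0(substr(ancestor, 1, ms_start - 1), ms,
                     substr(ancestor, ms_start + nchar(ms), L))
  # the conserved block wraps the unit boundary (promoter upstream, ETS
  # downstream in real rDNA), so tandem junction context is conserved and
  # unit-spanning reads anchor in every copy
  C <- floor(L * params$conserved_frac)
  Ch <- floor(C / 2)
  D <- params$mosaic_divergence
  if (D == 0) return(rep(ancestor, params$n_sources))
  rc0 <- min(0.001, D / 10)             # conserved-core per-source rate
  # per mutation event the expected edit burden is ~1.7 (85% SNPs of 1 edit,
  # 15% indels averaging ~5.5); divergence is measured in edits
  burden <- 0.85 + 0.15 * 5.5
  rd <- max(0, (D * L / 2 - rc0 * C) / ((L - C) * burden))
  gen_panel <- function(rd) {
    vapply(seq_len(params$n_sources), function(i) {
      head_cons <- mutate_bases(substr(ancestor, 1, Ch), rc0)
      igs <- mutate_bases(substr(ancestor, Ch + 1, L - (C - Ch)), rd,
                          p_sub = 0.85,
                          indel_len = function() sample(1:10, 1))
      tail_cons <- mutate_bases(substr(ancestor, L - (C - Ch) + 1, L), rc0)
      paste0(head_cons, igs, tail_cons)
    }, character(1))
  }
  measure <- function(panel) {
    n <- length(panel)
    tot <- 0; cnt <- 0
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      d <- cpp_edit_distance(panel[i], panel[j], -1)
      tot <- tot + d / mean(nchar(panel[c(i, j)]))
      cnt <- cnt + 1
    }
    tot / cnt
  }
  panel <- gen_panel(rd)
  for (iter in 1:6) {
    m <- measure(panel)
    if (abs(m - D) / D <= 0.06) break
    rd <- rd * D / max(m, 1e-6)
    panel <- gen_panel(rd)
  }
  m <- measure(panel)
  if (abs(m - D) / D > 0.2) {
    stop(sprintf("unreachable divergence target: measured %.4f vs target %.4f",
                 m, D))
  }
  panel
}

#' Generate mosaic morphs from a source panel
#'
#' Each morph switches among sources at Poisson(3)-many uniformly placed
#' breakpoints, then receives random mutations at `mutation_rate` (80%
#' substitutions, 20% single-base indels). Source segments are recorded in
#' half-open 0-based coordinates of the final (mutated) morph; the
#' pre-mutation mosaic and its segments are attached as attributes
#' `mosaic` and `mosaic_segments` for verification.
#'
#' @param panel character vector of source sequences.
#' @param params a [sim_params()] object.
#' @return list of morphs; each is a list with `morph_id`, `sequence`,
#'   `copy_count` and `source_segments` (data.frame start, end, source).
#' @export
generate_morphs <- function(panel, params) {
  stopifnot(length(panel) >= 1)
  set.seed(derive_seed(params$seed, 1L))
  law <- params$copy_count_law
  draw_copies <- function() {
    if (identical(law$type, "fixed")) return(as.integer(law$value))
    repeat {
      x <- 1L + stats::rgeom(1, law$p)
      if (x >= law$min && x <= law$max) return(as.integer(x))
    }
  }
  lapply(seq_len(params$n_morphs), function(m) {
    n_bp <- stats::rpois(1, 3)
    fracs <- sort(stats::runif(n_bp))
    bounds <- c(0, fracs, 1)
    src <- integer(length(bounds) - 1)
    src[1] <- sample(length(panel), 1)
    if (length(src) > 1) {
      for (i in 2:length(src)) {
        choices <- if (length(panel) > 1) setdiff(seq_along(panel), src[i - 1]) else 1L
        src[i] <- if (length(choices) == 1) choices else sample(choices, 1)
      }
    }
    pieces <- character(length(src))
    for (i in seq_along(src)) {
      lj <- nchar(panel[src[i]])
      a <- round(bounds[i] * lj); b <- round(bounds[i + 1] * lj)
      pieces[i] <- substr(panel[src[i]], a + 1, b)
    }
    mosaic <- paste(pieces, collapse = "")
    mosaic_segments <- data.frame(
      start = cumsum(c(0, nchar(pieces)))[seq_along(pieces)],
      end = cumsum(nchar(pieces)),
      source = src)
    # mutate each segment independently so segments still tile the morph
    mut_pieces <- vapply(pieces, function(p)
      mutate_bases(p, params$mutation_rate, p_sub = 0.8,
                   indel_len = function() 1L), character(1), USE.NAMES = FALSE)
    sequence <- paste(mut_pieces, collapse = "")
    segments <- data.frame(
      start = cumsum(c(0, nchar(mut_pieces)))[seq_along(mut_pieces)],
      end = cumsum(nchar(mut_pieces)),
      source = src)
    structure(list(morph_id = sprintf("morph_%02d", m),
                   sequence = sequence,
                   copy_count = draw_copies(),
                   source_segments = segments),
              mosaic = mosaic, mosaic_segments = mosaic_segments)
  })
}

#' Arrange morph copies into a tandem array
#'
#' @param morphs list of morphs from [generate_morphs()].
#' @param seed RNG seed for the copy shuffle.
#' @return list with `array_sequence`, `morphs`, and `unit_order` (a uniform
#'   random shuffle of the copy multiset).
#' @export
build_array <- function(morphs, seed = 1) {
  stopifnot(all(vapply(morphs, function(m) m$copy_count >= 1, logical(1))))
  set.seed(as.integer(seed))
  ids <- unlist(lapply(morphs, function(m) rep(m$morph_id, m$copy_count)))
  unit_order <- if (length(ids) > 1) sample(ids) else ids
  seq_by_id <- stats::setNames(vapply(morphs, `[[`, character(1), "sequence"),
                               vapply(morphs, `[[`, character(1), "morph_id"))
  structure(list(array_sequence = paste(seq_by_id[unit_order], collapse = ""),
                 morphs = morphs, unit_order = unit_order),
            class = "simulated_array")
}

#' Read profiles
#'
#' Length law is lognormal with the given sigma (log-scale sd); error rates
#' are per-base; `homopolymer_indel_weight` multiplies indel rates inside
#' runs of length >= 3. The HiFi-like default is 18 kb mean length with 0.2%
#' errors; the ONT-like default is 60 kb mean length (heavy-tailed) with 5%
#' errors and extra homopolymer indels.
#'
#' @param mean_length mean read length (bp).
#' @param sigma lognormal log-scale standard deviation.
#' @param sub_rate,ins_rate,del_rate per-base error rates.
#' @param homopolymer_indel_weight indel multiplier inside homopolymer runs.
#' @return a `read_profile` list.
#' @export
read_profile <- function(mean_length, sigma, sub_rate, ins_rate, del_rate,
                         homopolymer_indel_weight = 1) {
  stopifnot(mean_length > 0, sub_rate + ins_rate + del_rate <= 0.2,
            sub_rate >= 0, ins_rate >= 0, del_rate >= 0)
  structure(list(mean_length = mean_length, sigma = sigma,
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate,
                 homopolymer_indel_weight = homopolymer_indel_weight),
            class = "read_profile")
}

#' @rdname read_profile
#' @export
hifi_profile <- function(mean_length = 18000) {
  read_profile(mean_length, sigma = 0.25, sub_rate = 0.0012,
               ins_rate = 0.0004, del_rate = 0.0004,
               homopolymer_indel_weight = 1)
}

#' @rdname read_profile
#' @param mean_length mean read length (bp).
#' @export
ont_profile <- function(mean_length = 60000) {
  read_profile(mean_length, sigma = 0.9, sub_rate = 0.025,
               ins_rate = 0.012, del_rate = 0.013,
               homopolymer_indel_weight = 1.5)
}

#' Simulate reads from a tandem array
#'
#' Read start positions are uniform over the (linear) array; lengths are
#' drawn from the profile's lognormal law truncated at the remaining array
#' length; errors are injected per the profile with homopolymer bias; the
#' strand is uniform. The true origin interval and strand are recorded in
#' each read's description. Reads are drawn until total bases reach
#' `coverage` times the array length.
#'
#' @param array a `simulated_array` from [build_array()] (or any list with
#'   an `array_sequence` element / a bare sequence string).
#' @param profile a [read_profile()].
#' @param coverage target fold coverage (> 0).
#' @param seed RNG seed.
#' @return data.frame of sequence records (id, desc, seq, qual).
#' @export
simulate_reads <- function(array, profile, coverage, seed = 1) {
  stopifnot(coverage > 0)
  target_seq <- if (is.character(array)) array else array$array_sequence
  L <- nchar(target_seq)
  if (profile$mean_length > L) {
    warning("profile mean_length exceeds array length; reads are truncated")
  }
  set.seed(as.integer(seed))
  meanlog <- log(profile$mean_length) - profile$sigma^2 / 2
  target <- coverage * L
  total <- 0
  ids <- character(0); descs <- character(0); seqs <- character(0)
  i <- 0L
  while (total < target) {
    i <- i + 1L
    start <- floor(stats::runif(1) * L)    # 0-based
    len <- max(200L, round(stats::rlnorm(1, meanlog, profile$sigma)))
    len <- min(len, L - start)
    tmpl <- substr(target_seq, start + 1, start + len)
    obs <- cpp_inject_errors(tmpl, profile$sub_rate, profile$ins_rate,
                             profile$del_rate, profile$homopolymer_indel_weight)
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    if (strand == "-") obs <- cpp_revcomp(obs)
    ids <- c(ids, sprintf("read_%06d", i))
    descs <- c(descs, sprintf("origin=%d-%d strand=%s", start, start + len, strand))
    seqs <- c(seqs, obs)
    total <- total + nchar(obs)
  }
  out <- data.frame(id = ids, desc = descs, seq = seqs, stringsAsFactors = FALSE)
  out$qual <- vector("list", nrow(out))
  out
}

#' Simulate a complete dataset (panel, morphs, array, reads)
#'
#' Convenience wrapper running the full simulation under a single seed
#' (sub-seeds derive deterministically from `params$seed`).
#'
#' @param params a [sim_params()].
#' @param hifi,ont read profiles (NULL skips that read set).
#' @param hifi_coverage,ont_coverage fold coverages.
#' @return list with `panel`, `morphs`, `array`, `hifi`, `ont`.
#' @export
simulate_dataset <- function(params, hifi = hifi_profile(), ont = ont_profile(),
                             hifi_coverage = 35, ont_coverage = 120) {
  panel <- generate_source_panel(params)
  morphs <- generate_morphs(panel, params)
  array <- build_array(morphs, seed = derive_seed(params$seed, 2L))
  hifi_reads <- if (!is.null(hifi)) {
    simulate_reads(array, hifi, hifi_coverage, seed = derive_seed(params$seed, 3L))
  }
  ont_reads <- if (!is.null(ont)) {
    simulate_reads(array, ont, ont_coverage, seed = derive_seed(params$seed, 4L))
  }
  list(panel = panel, morphs = morphs, array = array,
       hifi = hifi_reads, ont = ont_reads)
}
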