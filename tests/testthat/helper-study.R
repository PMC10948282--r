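# One replicate of the scaled simulation study: 9 mosaic morphs (5 kb units,
# 4.4% average divergence = 4.2% mosaic + 0.2% random mutations), geometric
# copy counts in [1, 15] with the stated total of about 40 copies, HiFi-like
# reads at 35x and ONT-like ultralong reads at 60x (mean 25 kb, ~5% error),
# then the full ref-mode pipeline at matching scale.
study_copy_counts <- function(seed, n_morphs = 9) {
  set.seed(seed)
  repeat {
    x <- integer(n_morphs)
    for (i in seq_len(n_morphs)) {
      repeat {
        v <- 1L + stats::rgeom(1, 0.25)
        if (v <= 15L) { x[i] <- v; break }
      }
    }
    if (sum(x) >= 33 && sum(x) <= 46) return(x)
  }
}

study_replicate <- function(seed, out_dir = tempfile("study_")) {
  p <- sim_params(n_sources = 9, morph_length = 5000, n_morphs = 9,
                  mosaic_divergence = 0.042, mutation_rate = 0.002,
                  copy_count_law = list(type = "geometric", p = 0.25,
                                        min = 1, max = 15),
                  seed = seed)
  panel <- generate_source_panel(p)
  morphs <- generate_morphs(panel, p)
  counts <- study_copy_counts(ribomorph:::derive_seed(seed, 7L))
  for (i in seq_along(morphs)) morphs[[i]]$copy_count <- counts[i]
  array <- build_array(morphs, seed = ribomorph:::derive_seed(seed, 2L))
  hifi <- simulate_reads(array, hifi_profile(18000), 35,
                         seed = ribomorph:::derive_seed(seed, 3L))
  ont <- simulate_reads(array, ont_profile(25000), 60,
                        seed = ribomorph:::derive_seed(seed, 4L))
  cfg <- pipeline_config(reference = panel[1], hifi = hifi,
                         ont = ont, out_dir = out_dir,
                         approx_morph_size = 5000, k_graph = 31,
                         solid_min = 5, seed = seed)
  res <- suppressMessages(run_ref_pipeline(cfg))
  list(sim = list(panel = panel, morphs = morphs, array = array),
       res = res)
}
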