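# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# a small (100 kb) cascade fixture for unit tests
small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- synthetic_config(seed = 11L, genome_length = 100000L,
                            n_planted_motifs = 40L, n_genes = 80L)
    genome <- generate_genome(cfg)
    occ <- scan_motif(genome, cfg$motif)
    sample <- classify_6ma(
      generate_methylome_cascade(genome, cfg, sample_id = "fix"), occ)
    .fixture_cache$small <- list(cfg = cfg, genome = genome, occ = occ,
                                 sample = sample)
  }
  .fixture_cache$small
}

# full-scale (1 Mb, generator defaults) samples across several master seeds;
# used by the parameter-recovery and crosstalk checks
default_scale_samples <- function(seeds = 1:5) {
  key <- paste0("scale_", paste(seeds, collapse = "_"))
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- lapply(seeds, function(s) {
      cfg <- synthetic_config(seed = s)
      genome <- generate_genome(cfg)
      occ <- scan_motif(genome, cfg$motif)
      sm <- classify_6ma(
        generate_methylome_cascade(genome, cfg, sample_id = paste0("seed", s)),
        occ)
      list(cfg = cfg, genome = genome, sample = sm)
    })
  }
  .fixture_cache[[key]]
}

# a ready-made pipeline configuration over the disk bundle
pipeline_config <- function(out_dir) {
  b <- disk_bundle()
  labels <- c("control", "1G", "10G", "100G")
  meth <- vapply(labels, function(l) b$paths[[paste0("methylome_", l)]], character(1))
  degs <- c("control_vs_1G" = b$paths$deg_control_vs_1G,
            "control_vs_10G" = b$paths$deg_control_vs_10G,
            "control_vs_100G" = b$paths$deg_control_vs_100G)
  run_config(
    genome_path = b$paths$genome, topology = "circular",
    methylome_paths = meth, annotation_path = b$paths$annotation,
    deg_paths = degs, out_dir = out_dir
  )
}

# an on-disk bundle for pipeline tests (written once into a session tempdir)
disk_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    dir <- file.path(tempdir(), "mct_bundle")
    cfg <- synthetic_config(seed = 23L, genome_length = 60000L,
                            n_planted_motifs = 25L, n_genes = 50L,
                            n_deg_base = 5L)
    paths <- suppressMessages(write_fixture_bundle(dir, cfg))
    .fixture_cache$bundle <- list(cfg = cfg, dir = dir, paths = paths)
  }
  .fixture_cache$bundle
}
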