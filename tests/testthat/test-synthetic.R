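test_that("generation is fully deterministic under a fixed master seed", {
  cfg <- synthetic_config(seed = 99L, genome_length = 30000L,
                          n_planted_motifs = 12L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$sequence, g2$sequence)
  s1 <- generate_methylome_cascade(g1, cfg)
  s2 <- generate_methylome_cascade(g2, cfg)
  expect_identical(s1$sites, s2$sites)
})

test_that("background composition and motif planting meet their guarantees", {
  cfg <- small_fixture()$cfg   # 100 kb, gc 0.61, 40 motifs
  g <- small_fixture()$genome
  comp <- base_composition(g)
  gc_hat <- (comp$C + comp$G) / g$length
  # empirical GC within 3 sigma of the binomial expectation
  sigma <- sqrt(0.61 * 0.39 / g$length)
  expect_lt(abs(gc_hat - 0.61), 3 * sigma + 0.002)  # planting/scrub drift allowance
  # the scan finds at least the planted copies (here: exactly, by scrubbing)
  occ <- small_fixture()$occ
  expect_gte(nrow(occ), cfg$n_planted_motifs)
  expect_equal(nrow(occ), cfg$n_planted_motifs)
})

test_that("degenerate cascade configurations produce exactly what they promise", {
  cfg0 <- synthetic_config(seed = 5L, genome_length = 30000L,
                           n_planted_motifs = 10L, o_per_m = 0,
                           n_4mc_target = 0L)
  g <- generate_genome(cfg0)
  sm <- generate_methylome_cascade(g, cfg0)
  # only M-6mA: every site is a motif target
  expect_true(all(sm$sites$mod_type == "6mA"))
  occ <- scan_motif(g, cfg0$motif)
  cl <- classify_6ma(sm, occ)
  expect_true(all(cl$sites$subtype == "M"))
  expect_equal(m_fraction(cl), 1)
  expect_equal(nrow(sm$sites), nrow(occ))
})

test_that("cascade output passes the read filter and the classify partition", {
  fix <- small_fixture()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_methylome(fix$sample, p, "tsv")
  back <- suppressMessages(read_methylome(p, "tsv", genome = fix$genome))
  expect_equal(nrow(back$sites), nrow(fix$sample$sites))  # nothing filtered
  s <- fix$sample$sites
  expect_equal(sum(s$subtype == "M") + sum(s$subtype == "O"),
               sum(s$mod_type == "6mA"))
})

test_that("sub-threshold records injected into a fixture are filtered on read", {
  fix <- small_fixture()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_methylome(fix$sample, p, "tsv")
  aden <- which(strsplit(fix$genome$sequence, "")[[1]] == "A")
  free <- setdiff(aden, fix$sample$sites$position)[1:3]
  bad <- sprintf("corrupt\t%s\t%d\t+\t6mA\t%d\t%d", fix$genome$contig_id,
                 free, c(99L, 150L, 40L), c(50L, 25L, 50L))
  cat(bad, file = p, sep = "\n", append = TRUE)
  back <- suppressMessages(read_methylome(p, "tsv", genome = fix$genome))
  expect_equal(nrow(back$sites), nrow(fix$sample$sites))
  expect_equal(attr(back, "n_filtered"), 3L)
})

test_that("sample families share all M-6mA and scale overlap with retention", {
  fix <- small_fixture()
  cfg1 <- synthetic_config(seed = 31L, genome_length = 100000L,
                           n_planted_motifs = 40L, retention_rho = 1)
  fam1 <- generate_sample_family(fix$genome, cfg1, n_conditions = 3L)
  fam1 <- lapply(fam1, classify_6ma, occurrences = fix$occ)
  for (cls in c("4mC", "6mA", "O6mA")) {
    ov <- site_overlap(fam1, cls)
    expect_equal(ov$fraction_shared_per_sample, rep(1, 3),
                 tolerance = 1e-12, label = cls)
  }

  cfg0 <- synthetic_config(seed = 32L, genome_length = 100000L,
                           n_planted_motifs = 40L, retention_rho = 0)
  fam0 <- generate_sample_family(fix$genome, cfg0, n_conditions = 3L)
  fam0 <- lapply(fam0, classify_6ma, occurrences = fix$occ)
  # M positions identical in every condition
  m_sets <- lapply(fam0, function(x) x$sites$position[x$sites$subtype == "M"])
  expect_identical(m_sets[[1]], m_sets[[2]])
  expect_identical(m_sets[[1]], m_sets[[3]])
  # 6mA intersection contains the M set; O-6mA intersection is near zero
  ov6 <- site_overlap(fam0, "6mA")
  expect_gte(ov6$intersection_all, length(m_sets[[1]]))
  ovo <- site_overlap(fam0, "O6mA")
  expect_lte(ovo$intersection_all, ceiling(0.05 * min(ovo$counts)))
  # class counts regrown to the first condition's counts
  n4 <- vapply(fam0, function(x) sum(x$sites$mod_type == "4mC"), integer(1))
  expect_true(all(n4 == n4[1]))
})

test_that("the crosstalk signature holds: O-6mA sit nearer 4mC than M-6mA do", {
  fix <- small_fixture()
  o5 <- cumulative_curve(to_4mc_distances(fix$sample, "O6mA"), 5)$cumulative_fraction
  m5 <- cumulative_curve(to_4mc_distances(fix$sample, "M6mA"), 5)$cumulative_fraction
  expect_gt(o5, m5)
  expect_gt(o5, 0.5)
})

test_that("annotations tile without overlap and DEG counts follow intensity", {
  fix <- small_fixture()
  cfg <- fix$cfg
  ann <- generate_annotation_and_degs(fix$genome, cfg)
  feats <- ann$features
  expect_equal(nrow(feats), cfg$n_genes)
  expect_true(all(feats$end <= fix$genome$length))
  expect_true(all(feats$start[-1] > feats$end[-nrow(feats)]))  # non-overlapping

  n_deg <- vapply(ann$deg_tables, function(t) sum(t$direction != "ns"), integer(1))
  expect_true(all(diff(n_deg) > 0))  # strictly increasing with intensity
  expect_equal(unname(n_deg), c(1L, 2L, 3L) * cfg$n_deg_base)

  cfg_none <- synthetic_config(seed = 12L, genome_length = 100000L,
                               n_planted_motifs = 40L, n_genes = 30L,
                               n_deg_base = 0L)
  ann0 <- generate_annotation_and_degs(fix$genome, cfg_none)
  expect_true(all(ann0$deg_tables[[1]]$direction == "ns"))
})

test_that("infeasible configurations fail loudly", {
  cfg <- synthetic_config(seed = 3L, genome_length = 300L, n_planted_motifs = 40L)
  expect_error(generate_genome(cfg), "infeasible")
  g <- generate_genome(synthetic_config(seed = 3L, genome_length = 5000L,
                                        n_planted_motifs = 4L))
  cfg_big <- synthetic_config(seed = 3L, genome_length = 5000L,
                              n_planted_motifs = 4L, n_4mc_target = 5000L)
  expect_error(generate_methylome_cascade(g, cfg_big), "n_4mc_target|gap law")
})
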