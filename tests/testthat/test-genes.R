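lin_genome <- function(n = 6000) {
  set.seed(801)
  new_genome_seq("chr", random_dna(n, gc = 0.6), "linear")
}

test_that("upstream windows are strand-aware, clipped and never overlap the body", {
  g <- lin_genome()
  plus <- list(gene_id = "p", start = 1000L, end = 2000L, strand = "+")
  up <- upstream_region(plus, 200L, g)
  expect_equal(c(up$start, up$end), c(800L, 999L))
  expect_equal(attr(up, "achieved_length"), 200L)

  minus <- list(gene_id = "m", start = 4000L, end = 5000L, strand = "-")
  upm <- upstream_region(minus, 200L, g)
  expect_equal(c(upm$start, upm$end), c(5001L, 5200L))

  edge <- list(gene_id = "e", start = 50L, end = 400L, strand = "+")
  upe <- upstream_region(edge, 200L, g)
  expect_equal(c(upe$start, upe$end), c(1L, 49L))
  expect_equal(attr(upe, "achieved_length"), 49L)

  # circular genomes wrap into two forward intervals
  gc_ <- new_genome_seq("chr", strrep("ACGT", 100), "circular")
  upw <- upstream_region(list(gene_id = "w", start = 50L, end = 120L, strand = "+"),
                         200L, gc_)
  expect_equal(attr(upw, "achieved_length"), 200L)
  expect_equal(nrow(upw), 2L)
  expect_equal(upw$start[1], 250L)  # wraps from 400 back past the origin
  expect_equal(upw$end[2], 49L)
})

test_that("feature methylation levels equal a per-base recount", {
  g <- lin_genome()
  feats <- data.frame(gene_id = c("a", "b"), contig = "chr",
                      start = c(101L, 301L), end = c(300L, 700L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  cg <- letter_pos <- which(strsplit(g$sequence, "")[[1]] %in% c("C", "G"))
  pos <- cg[cg >= 101 & cg <= 500][c(1, 5, 20)]
  base <- substring(g$sequence, pos, pos)
  sm <- new_methylome_sample(
    site_df(pos, ifelse(base == "C", "+", "-"), "4mC"), "s", genome = g)
  fl <- feature_methylation(sm, feats, g, "body", "4mC")
  for (i in 1:2) {
    want <- brute_feature_level(pos, g$sequence, feats$start[i], feats$end[i],
                                c("C", "G"))
    expect_equal(fl$site_count[i], want$site_count)
    expect_equal(fl$modifiable_bases[i], want$modifiable_bases)
    expect_equal(fl$level[i], want$level)
  }

  # region without modifiable bases is flagged, not an error
  g2 <- new_genome_seq("chr", paste0("CC", strrep("A", 50), "CC"), "linear")
  sm2 <- new_methylome_sample(site_df(1L, "+", "4mC"), "s", genome = g2)
  feats2 <- data.frame(gene_id = "z", contig = "chr", start = 10L, end = 40L,
                       strand = "+", stringsAsFactors = FALSE)
  fl2 <- feature_methylation(sm2, feats2, g2, "body", "4mC")
  expect_false(fl2$level_defined)
  expect_true(is.na(fl2$level))
})

test_that("random genes on the cascade fixture match the recount oracle", {
  fix <- small_fixture()
  g <- fix$genome
  set.seed(802)
  starts <- sort(sample.int(g$length - 2000L, 25))
  feats <- data.frame(gene_id = sprintf("r%02d", 1:25), contig = g$contig_id,
                      start = starts, end = starts + sample(200:1500, 25, TRUE),
                      strand = sample(c("+", "-"), 25, TRUE),
                      stringsAsFactors = FALSE)
  s <- fix$sample$sites
  for (cls in c("4mC", "O6mA")) {
    fl <- feature_methylation(fix$sample, feats, g, "body", cls)
    pos <- if (cls == "4mC") s$position[s$mod_type == "4mC"] else
      s$position[s$subtype == "O"]
    letters <- if (cls == "4mC") c("C", "G") else c("A", "T")
    for (i in seq_len(nrow(feats))) {
      want <- brute_feature_level(unique(pos), g$sequence,
                                  feats$start[i], feats$end[i], letters)
      expect_equal(fl$site_count[i], want$site_count)
      expect_equal(fl$level[i], want$level)
    }
  }
})

test_that("a disjoint tiling of the genome conserves total site counts", {
  fix <- small_fixture()
  g <- fix$genome
  edges <- seq(1L, g$length + 1L, by = 5000L)
  feats <- data.frame(gene_id = sprintf("t%02d", seq_len(length(edges) - 1)),
                      contig = g$contig_id,
                      start = edges[-length(edges)],
                      end = edges[-1] - 1L, strand = "+",
                      stringsAsFactors = FALSE)
  fl <- feature_methylation(fix$sample, feats, g, "body", "4mC")
  expect_equal(sum(fl$site_count),
               length(unique(fix$sample$sites$position[fix$sample$sites$mod_type == "4mC"])))
})

test_that("genome level shares units with feature levels and the percentage", {
  fix <- small_fixture()
  comp <- base_composition(fix$genome)
  lvl <- genome_level(fix$sample, comp, "4mC")
  expect_equal(lvl, methylation_percentage(fix$sample, comp, "4mC") / 100)
  expect_gte(lvl, 0)
})

test_that("DEG categorization counts below-genome and zero-level genes per direction", {
  degs <- data.frame(gene_id = c("a", "b", "c", "d"),
                     direction = c("down", "down", "down", "up"),
                     stringsAsFactors = FALSE)
  levels <- data.frame(gene_id = c("a", "b", "c", "d"),
                       level = c(0, 0.01, 0.05, 0.5),
                       stringsAsFactors = FALSE)
  s <- categorize_degs(degs, levels, genome_lvl = 0.02)
  down <- s[s$direction == "down", ]
  expect_equal(down$n_lower_than_genome, 2L)
  expect_equal(down$n_zero, 1L)
  expect_equal(down$fraction_lower, 2 / 3)
  up <- s[s$direction == "up", ]
  expect_equal(up$n_lower_than_genome, 0L)
  expect_equal(up$n_zero, 0L)
  expect_true(all(s$n_zero <= s$n_lower_than_genome))

  expect_error(categorize_degs(
    data.frame(gene_id = "zz", direction = "up"), levels, 0.02), "missing")
})

test_that("Pearson correlation equals the closed-form product-moment formula", {
  x <- 1:5
  expect_equal(pearson_correlation(x, 2 * x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)

  y <- c(2, 1, 4, 3, 6)
  res <- pearson_correlation(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_direct)
  t_stat <- r_direct * sqrt(3 / (1 - r_direct^2))
  expect_equal(res$p, 2 * pt(-abs(t_stat), df = 3))

  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:4, 1:5), "length")
})

test_that("the per-gene report recomposes individual operations", {
  fix <- small_fixture()
  g <- fix$genome
  feats <- data.frame(gene_id = c("mt1", "mt2"), contig = g$contig_id,
                      start = c(1001L, 50001L), end = c(2000L, 51000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  degs <- list(c1 = deg_table(data.frame(gene_id = c("mt1", "mt2"),
                                         log2fc = c(2, 0.1),
                                         padj = c(0.01, 0.9))))
  samples <- list(control = fix$sample)
  rep <- methyltransferase_report(samples, feats, g, degs, c("mt1", "mt2"))
  fl <- feature_methylation(fix$sample, feats, g, "body", "4mC")
  expect_equal(rep$level_control, fl$level)
  expect_equal(rep$deg_c1, c("up", "ns"))
  expect_equal(nrow(methyltransferase_report(samples, feats, g, degs, character(0))), 0L)
  expect_error(methyltransferase_report(samples, feats, g, degs, "nope"), "unknown gene")
})
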