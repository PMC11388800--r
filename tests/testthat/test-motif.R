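test_that("motif occurrences map to the correct strand and target coordinates", {
  motif <- motif_spec()  # GTACAG, second adenine at 0-based offset 4

  g <- new_genome_seq("g", "AAGTACAGTT", "linear")
  occ <- scan_motif(g, motif)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$strand, "+")
  expect_equal(occ$start, 3L)
  expect_equal(occ$target_position, 7L)

  # forward 3..8 = CTGTAC = reverse complement of GTACAG: minus-strand hit,
  # 5' end on its own strand at forward 8, target at 8 - 4 = 4
  g2 <- new_genome_seq("g", "AACTGTACTT", "linear")
  occ2 <- scan_motif(g2, motif)
  expect_equal(nrow(occ2), 1L)
  expect_equal(occ2$strand, "-")
  expect_equal(occ2$start, 8L)
  expect_equal(occ2$target_position, 4L)

  # overlapping matches are all reported
  g3 <- new_genome_seq("g", "GTACAGTACAG", "linear")
  occ3 <- scan_motif(g3, motif)
  expect_equal(sort(occ3$start), c(1L, 6L))
  expect_equal(occ3$strand, c("+", "+"))
})

test_that("motif spec validates the target base", {
  expect_error(motif_spec("GTACAG", 3L), "must be A")  # offset 3 is C
  expect_silent(motif_spec("GTACAG", 2L))              # first adenine is fine
  expect_error(motif_spec("GTACAG", 6L), "outside")
  expect_error(motif_spec("GTACNG"), "A/C/G/T")
})

test_that("scan_motif equals a naive double-strand sliding window on random sequences", {
  motif <- motif_spec()
  set.seed(501)
  for (i in 1:12) {
    seq <- random_dna(2000, gc = 0.61)
    g <- new_genome_seq("g", seq, "linear")
    got <- scan_motif(g, motif)
    want <- naive_scan(seq, motif$sequence, motif$target_offset)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$target_position, want$target_position)
  }
})

test_that("circular scanning reports origin-spanning occurrences once", {
  motif <- motif_spec()
  # GTACAG split across the origin: ...GTA | CAG...
  seq <- paste0("CAG", strrep("T", 20), "GTA")
  g_circ <- new_genome_seq("g", seq, "circular")
  occ <- scan_motif(g_circ, motif)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$start, 24L)       # forward coordinate of the G
  expect_equal(occ$target_position, 2L)  # wraps: 24 + 4 -> position 2
  # the same sequence read as linear has no match
  g_lin <- new_genome_seq("g", seq, "linear")
  expect_equal(nrow(scan_motif(g_lin, motif)), 0L)
})

test_that("classification is strand-specific, exact and partition-complete", {
  g <- new_genome_seq("g", "AAGTACAGTT", "linear")
  occ <- scan_motif(g, motif_spec())  # target (7, +)
  sm <- new_methylome_sample(
    site_df(c(7L, 10L, 2L), c("+", "-", "+"), "6mA", contig = "g"), "s",
    genome = g)
  cl <- classify_6ma(sm, occ)
  sub <- cl$sites$subtype[order(cl$sites$position)]
  expect_equal(sub, c("O", "M", "O"))  # positions 2, 7, 10

  # strand mismatch stays O: a 6mA on '-' at the '+' target is not anchored
  sm2 <- new_methylome_sample(site_df(7L, "-", "6mA", contig = "g"), "s")
  expect_equal(classify_6ma(sm2, occ)$sites$subtype, "O")

  # empty occurrence list classifies everything O
  cl0 <- classify_6ma(sm, occ[0, ])
  expect_true(all(cl0$sites$subtype[cl0$sites$mod_type == "6mA"] == "O"))

  # partition identity and idempotence on the cascade fixture
  fix <- small_fixture()
  s <- fix$sample$sites
  n6 <- sum(s$mod_type == "6mA")
  expect_equal(sum(s$subtype == "M") + sum(s$subtype == "O"), n6)
  again <- classify_6ma(fix$sample, fix$occ)
  expect_identical(again$sites, s)
})

test_that("m_fraction agrees with an independent set-membership count", {
  fix <- small_fixture()
  sm <- fix$sample
  targets <- paste(fix$occ$target_position, fix$occ$strand)
  s6 <- sm$sites[sm$sites$mod_type == "6mA", ]
  oracle <- mean(paste(s6$position, s6$strand) %in% targets)
  expect_equal(m_fraction(sm), oracle)

  # unclassified samples refuse; empty 6mA flagged NA
  raw <- new_methylome_sample(site_df(5L, "+", "6mA"), "s")
  expect_error(m_fraction(raw), "not classified")
  only4 <- classify_6ma(new_methylome_sample(site_df(6L, "+", "4mC"), "s"), fix$occ)
  expect_warning(res <- m_fraction(only4), "no 6mA")
  expect_true(is.na(res))
})

test_that("every reported target position carries A on its own strand", {
  fix <- small_fixture()
  occ <- fix$occ
  base <- substring(fix$genome$sequence, occ$target_position, occ$target_position)
  expect_true(all(ifelse(occ$strand == "+", base == "A", base == "T")))
})
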