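test_that("adjacent distances handle linear, circular and degenerate inputs", {
  expect_equal(adjacent_distances(c(10, 12, 25), "linear")$distances, c(2L, 13L))
  expect_equal(adjacent_distances(c(10, 12, 25), "circular", genome_length = 100)$distances,
               c(2L, 13L, 85L))
  expect_equal(adjacent_distances(7, "linear")$distances, integer(0))
  expect_error(adjacent_distances(c(5, 3), "linear"), "sorted")
  expect_error(adjacent_distances(c(3, 3, 5), "linear"), "sorted")
})

test_that("nearest cross distances match the O(n^2) oracle and tie rule", {
  expect_equal(nearest_cross_distances(10, c(7, 14))$distances, 3L)
  expect_equal(nearest_cross_distances(c(5, 20), 6)$distances, c(1L, 14L))
  # equidistant neighbours yield one value, not two
  expect_equal(nearest_cross_distances(10, c(7, 13))$distances, 3L)
  expect_error(nearest_cross_distances(5, integer(0)), "empty")

  set.seed(601)
  for (i in 1:20) {
    from <- sort(sample.int(5000, sample(1:200, 1)))
    to <- sort(sample.int(5000, sample(1:200, 1)))
    got <- nearest_cross_distances(from, to)$distances
    expect_equal(as.numeric(got), brute_nearest(from, to))
  }
})

test_that("binning follows the (0,10] ... (240,250] convention and conserves counts", {
  ds <- distance_set(1:250, "4mC")
  h <- bin_histogram(ds)
  expect_equal(h$counts, rep(10L, 25))
  expect_equal(h$n_excluded, 0L)

  h251 <- bin_histogram(distance_set(251, "4mC"))
  expect_equal(sum(h251$counts), 0L)
  expect_equal(h251$n_excluded, 1L)

  h10 <- bin_histogram(distance_set(10, "4mC"))
  expect_equal(h10$counts[1], 1L)  # 10 falls in (0,10]
  h250 <- bin_histogram(distance_set(250, "4mC"))
  expect_equal(h250$counts[25], 1L)  # 250 included in the last bin

  expect_error(bin_histogram(ds, max_distance = 251), "divisible")

  # conservation on random distance sets, including zeros and overflow
  set.seed(602)
  for (i in 1:10) {
    d <- sample(0:500, 200, replace = TRUE)
    h <- bin_histogram(distance_set(d, "4mC", "6mA", kind = "nearest"))
    expect_equal(sum(h$counts) + h$n_excluded + h$n_zero, length(d))
  }
})

test_that("power-law fit recovers noiseless parameters and the flat limit", {
  x <- seq(5, 245, by = 10)
  h <- structure(list(bin_edges = seq(0, 250, 10), mid = x,
                      counts = 100 * x^-1, n_zero = 0L, n_excluded = 0L,
                      n = 25L, context = NULL),
                 class = "binned_histogram")
  f <- fit_power_law(h)
  expect_equal(f$a, 100, tolerance = 1e-6)
  expect_equal(f$b, -1, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-6)

  h$counts <- rep(50, 25)
  f2 <- fit_power_law(h)
  expect_equal(f2$b, 0, tolerance = 1e-6)
  expect_true(is.na(f2$r_squared))  # SS_tot = 0: undefined

  h$counts <- c(5, 3, rep(0, 23))
  expect_error(fit_power_law(h), "at least 3 bins")
})

test_that("fitted exponent tracks the log-log OLS oracle on cascade data", {
  fix <- small_fixture()
  pos <- sort(unique(fix$sample$sites$position[fix$sample$sites$mod_type == "4mC"]))
  h <- bin_histogram(adjacent_distances(pos, "circular", fix$genome$length))
  f <- fit_power_law(h)
  keep <- h$counts > 0
  ols <- lm(log(h$counts[keep]) ~ log(h$mid[keep]))
  expect_lt(f$b, 0)
  expect_equal(f$b, unname(coef(ols)[2]), tolerance = 0.2)
})

test_that("cumulative curves respect strict/non-strict boundaries and monotonicity", {
  ds <- distance_set(c(1, 1, 3, 7), "O6mA", "4mC", kind = "nearest")
  expect_equal(cumulative_curve(ds, 5)$cumulative_fraction, 0.75)
  expect_equal(cumulative_curve(ds, 1)$cumulative_fraction, 0)
  expect_equal(cumulative_curve(ds, 1, strict = FALSE)$cumulative_fraction, 0.5)
  expect_equal(cumulative_curve(ds, 1e9)$cumulative_fraction, 1)
  expect_error(cumulative_curve(distance_set(integer(0), "4mC"), 5), "empty")
  expect_error(cumulative_curve(ds, c(5, 2)), "increasing")

  set.seed(603)
  d <- distance_set(sample.int(300, 100, replace = TRUE), "4mC")
  t <- c(1, 5, 20, 100, 400)
  strict <- cumulative_curve(d, t, strict = TRUE)$cumulative_fraction
  loose <- cumulative_curve(d, t, strict = FALSE)$cumulative_fraction
  expect_true(all(diff(strict) >= 0))
  expect_true(all(strict <= loose))
})

test_that("O-to-M distances equal the brute-force per-site minimum", {
  occ <- data.frame(contig = "chr", start = c(92, 106), strand = "+",
                    target_position = c(96, 110))
  sm <- classify_6ma(
    new_methylome_sample(site_df(c(96L, 100L, 110L), "+", "6mA"), "s"), occ)
  expect_equal(o_to_m_distances(sm)$distances, 4L)

  # no O-6mA: empty result; no M-6mA: error
  sm_all_m <- classify_6ma(
    new_methylome_sample(site_df(c(96L, 110L), "+", "6mA"), "s"), occ)
  expect_equal(o_to_m_distances(sm_all_m)$distances, integer(0))
  sm_no_m <- classify_6ma(
    new_methylome_sample(site_df(50L, "+", "6mA"), "s"), occ[0, ])
  expect_error(o_to_m_distances(sm_no_m), "no M-6mA")

  fix <- small_fixture()
  got <- o_to_m_distances(fix$sample)$distances
  s <- fix$sample$sites
  m_pos <- sort(unique(s$position[s$subtype == "M"]))
  o_pos <- sort(unique(s$position[s$subtype == "O"]))
  expect_equal(as.numeric(got), brute_nearest(o_pos, m_pos))
})

test_that("power law decays in double- and single-strand calculations alike", {
  fix <- small_fixture()
  for (mode in c("double", "positive", "negative")) {
    pos <- methcrosstalk:::class_positions(fix$sample, "4mC", mode)
    h <- bin_histogram(adjacent_distances(pos, "circular", fix$genome$length,
                                          strand_mode = mode))
    f <- fit_power_law(h)
    expect_lt(f$b, 0)
  }
})
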