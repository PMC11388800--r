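#' Construct a distance set
#'
#' A labelled multiset of inter-site distances (bp). The context records
#' which site classes the distances run between, which strand selection was
#' used (`positive`/`negative` single strand, or `double` = both strands
#' pooled by forward coordinate) and whether distances are between adjacent
#' members of one set or from each site to its nearest neighbour in another
#' set.
#'
#' @param distances Integer vector of distances (bp), order irrelevant.
#' @param from_class,to_class One of `4mC`, `6mA`, `M6mA`, `O6mA`.
#' @param strand_mode `positive`, `negative` or `double`.
#' @param kind `adjacent` or `nearest`.
#' @return A `distance_set` object.
#' @export
distance_set <- function(distances, from_class, to_class = from_class,
                         strand_mode = c("double", "positive", "negative"),
                         kind = c("adjacent", "nearest")) {
  strand_mode <- match.arg(strand_mode)
  kind <- match.arg(kind)
  distances <- as.integer(distances)
  if (any(distances < 0L, na.rm = TRUE)) stop("negative distance")
  structure(
    list(
      distances = distances,
      context = list(from_class = from_class, to_class = to_class,
                     strand_mode = strand_mode, kind = kind)
    ),
    class = "distance_set"
  )
}

#' @export
print.distance_set <- function(x, ...) {
  cat(sprintf("<distance_set> %s->%s (%s, %s): n=%d%s\n",
              x$context$from_class, x$context$to_class, x$context$kind,
              x$context$strand_mode, length(x$distances),
              if (length(x$distances) > 0)
                sprintf(", median=%g", stats::median(x$distances)) else ""))
  invisible(x)
}

#' Distances between adjacent sites of one set
#'
#' Differences of consecutive sorted forward coordinates. On circular
#' genomes the wrap-around gap `genome_length - (max - min)` is included, so
#' n positions yield n distances (n - 1 on linear genomes). Fewer than two
#' positions yield an empty set.
#'
#' @param positions Sorted, deduplicated coordinate vector.
#' @param topology `"linear"` or `"circular"`.
#' @param genome_length Required for circular topology.
#' @param from_class,strand_mode Context labels passed to [distance_set()].
#' @return A `distance_set` of kind `adjacent`.
#' @export
adjacent_distances <- function(positions, topology = c("linear", "circular"),
                               genome_length = NULL, from_class = "4mC",
                               strand_mode = "double") {
  topology <- match.arg(topology)
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be sorted ascending and deduplicated")
  }
  if (length(positions) < 2L) {
    return(distance_set(integer(0), from_class, from_class, strand_mode, "adjacent"))
  }
  d <- diff(positions)
  if (topology == "circular") {
    if (is.null(genome_length)) stop("genome_length required for circular topology")
    d <- c(d, genome_length - (max(positions) - min(positions)))
  }
  distance_set(d, from_class, from_class, strand_mode, "adjacent")
}

#' Nearest-neighbour distances from one set of sites to another
#'
#' For each `from` position, the minimum absolute coordinate difference to
#' any `to` position. Equidistant left/right neighbours contribute that
#' distance once (one value per `from` site, never two).
#'
#' @param from_positions,to_positions Sorted coordinate vectors;
#'   `to_positions` must be non-empty.
#' @param from_class,to_class,strand_mode Context labels.
#' @return A `distance_set` of kind `nearest`, one value per `from` site.
#' @export
nearest_cross_distances <- function(from_positions, to_positions,
                                    from_class = "6mA", to_class = "4mC",
                                    strand_mode = "double") {
  if (length(to_positions) == 0L) stop("to_positions is empty")
  if (is.unsorted(from_positions)) stop("from_positions must be sorted")
  if (is.unsorted(to_positions)) stop("to_positions must be sorted")
  if (length(from_positions) == 0L) {
    return(distance_set(integer(0), from_class, to_class, strand_mode, "nearest"))
  }
  idx <- findInterval(from_positions, to_positions)
  left <- ifelse(idx >= 1L, from_positions - to_positions[pmax(idx, 1L)], NA_integer_)
  right <- ifelse(idx < length(to_positions),
                  to_positions[pmin(idx + 1L, length(to_positions))] - from_positions,
                  NA_integer_)
  d <- pmin(left, right, na.rm = TRUE)
  distance_set(d, from_class, to_class, strand_mode, "nearest")
}

#' Bin distances into the standard 25-bin frequency histogram
#'
#' Distances up to `max_distance` (inclusive) are divided into `n_bins`
#' equal left-open right-closed bins: (0,10], (10,20], ..., (240,250] with
#' the defaults. Larger distances are counted in `n_excluded`; zero
#' distances (possible only for cross-class pairs) are counted in `n_zero`.
#' Counts are raw frequencies, not densities.
#'
#' @param ds A `distance_set`.
#' @param max_distance Upper end of the binned range (bp).
#' @param n_bins Number of equal bins; must divide `max_distance`.
#' @return A `binned_histogram`: `bin_edges` (length `n_bins + 1`),
#'   `mid` (bin midpoints), `counts`, `n_excluded`, `n_zero`, `n`.
#' @export
bin_histogram <- function(ds, max_distance = 250L, n_bins = 25L) {
  max_distance <- as.integer(max_distance)
  n_bins <- as.integer(n_bins)
  if (max_distance %% n_bins != 0L) stop("max_distance must be divisible by n_bins")
  width <- max_distance %/% n_bins
  d <- ds$distances
  n_zero <- sum(d == 0L)
  n_excluded <- sum(d > max_distance)
  in_range <- d[d >= 1L & d <= max_distance]
  counts <- tabulate(((in_range - 1L) %/% width) + 1L, nbins = n_bins)
  edges <- seq(0L, max_distance, by = width)
  structure(
    list(
      bin_edges = edges,
      mid = edges[-length(edges)] + width / 2,
      counts = counts,
      n_zero = n_zero,
      n_excluded = n_excluded,
      n = length(d),
      context = ds$context
    ),
    class = "binned_histogram"
  )
}

#' @export
print.binned_histogram <- function(x, ...) {
  cat(sprintf("<binned_histogram> %d bins of %g bp, n=%d (excluded>%d: %d, zero: %d)\n",
              length(x$counts), diff(x$bin_edges[1:2]), x$n,
              max(x$bin_edges), x$n_excluded, x$n_zero))
  invisible(x)
}

#' Allometric (power-law) fit of a distance-frequency histogram
#'
#' Fits `y = a * x^b` by nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) to the positive-count bins, with `x` the bin midpoint
#' and `y` the raw count. Starting values come from ordinary least squares
#' on `(log x, log y)`; `a` is constrained positive. R-squared is computed
#' on the linear scale, `1 - SS_res / SS_tot`, and reported as `NA` when all
#' counts are equal (`SS_tot = 0`). Zero-count bins are excluded from the
#' fit (their log frequency is undefined) but still appear in exports.
#'
#' @param hist A `binned_histogram` with at least 3 positive-count bins.
#' @return A `power_law_fit`: `a`, `b`, `r_squared`, `n_bins_fit`, plus the
#'   `x`/`y` vectors used.
#' @export
fit_power_law <- function(hist) {
  pos <- hist$counts > 0
  if (sum(pos) < 3L) stop("power-law fit needs at least 3 bins with positive counts")
  x <- hist$mid[pos]
  y <- as.numeric(hist$counts[pos])

  ols <- stats::lm(log(y) ~ log(x))
  b0 <- unname(stats::coef(ols)[2])
  a0 <- exp(unname(stats::coef(ols)[1]))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * x^b,
      start = list(a = a0, b = b0),
      lower = c(a = .Machine$double.eps, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    a <- a0; b <- b0
    fitted_y <- a * x^b
  } else {
    cf <- stats::coef(fit)
    a <- unname(cf["a"]); b <- unname(cf["b"])
    fitted_y <- stats::fitted(fit)
  }
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  r_squared <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  structure(
    list(a = a, b = b, r_squared = r_squared,
         n_bins_fit = length(x), x = x, y = y,
         context = hist$context),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^%.4g, R^2 = %s (%d bins)\n",
              x$a, x$b,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              x$n_bins_fit))
  invisible(x)
}

#' Cumulative fraction of distances below thresholds
#'
#' At threshold `t`, the fraction of distances strictly less than `t`
#' (`strict = TRUE`, the default, matching statements like "a distance of
#' less than 5 bp") or less than or equal to `t`.
#'
#' @param ds A non-empty `distance_set`.
#' @param thresholds Increasing vector of bp thresholds.
#' @param strict Use `<` (TRUE) or `<=` (FALSE).
#' @return A `cumulative_curve`: `thresholds`, `cumulative_fraction`,
#'   `strict`, `n`.
#' @export
cumulative_curve <- function(ds, thresholds, strict = TRUE) {
  d <- ds$distances
  if (length(d) == 0L) stop("empty distance set")
  if (is.unsorted(thresholds, strictly = TRUE)) stop("thresholds must be strictly increasing")
  frac <- vapply(thresholds,
                 function(t) if (strict) mean(d < t) else mean(d <= t),
                 numeric(1))
  structure(
    list(thresholds = thresholds, cumulative_fraction = frac,
         strict = strict, n = length(d), context = ds$context),
    class = "cumulative_curve"
  )
}

# forward coordinates of sites of one class, pooled or single-strand
class_positions <- function(sample, class,
                            strand_mode = c("double", "positive", "negative")) {
  strand_mode <- match.arg(strand_mode)
  s <- sample$sites
  keep <- switch(class,
    "4mC" = s$mod_type == "4mC",
    "6mA" = s$mod_type == "6mA",
    "M6mA" = s$mod_type == "6mA" & s$subtype == "M",
    "O6mA" = s$mod_type == "6mA" & s$subtype == "O",
    stop("unknown site class: ", class)
  )
  if (class %in% c("M6mA", "O6mA") && any(s$subtype[s$mod_type == "6mA"] == "unset")) {
    stop("sample not classified; run classify_6ma() first")
  }
  if (strand_mode == "positive") keep <- keep & s$strand == "+"
  if (strand_mode == "negative") keep <- keep & s$strand == "-"
  sort(unique(s$position[keep]))
}

#' Distances from each O-6mA to its nearest M-6mA
#'
#' Forward-coordinate nearest-neighbour distances, both strands pooled.
#'
#' @param sample A classified `methylome_sample` containing at least one
#'   M-6mA.
#' @return A `distance_set` (`O6mA -> M6mA`, kind `nearest`); empty when
#'   the sample has no O-6mA.
#' @export
o_to_m_distances <- function(sample) {
  m_pos <- class_positions(sample, "M6mA")
  if (length(m_pos) == 0L) stop("no M-6mA in sample")
  o_pos <- class_positions(sample, "O6mA")
  nearest_cross_distances(o_pos, m_pos, from_class = "O6mA", to_class = "M6mA")
}

#' Nearest-4mC distance sets for O-6mA and M-6mA
#'
#' The crosstalk comparison: for each O-6mA (resp. M-6mA), the distance to
#' the nearest 4mC. The reverse direction (for each 4mC, the nearest site of
#' the 6mA subtype) is available via `per_4mc = TRUE`.
#'
#' @param sample A classified `methylome_sample`.
#' @param subtype `"O6mA"` or `"M6mA"`.
#' @param per_4mc If TRUE, measure from each 4mC to the nearest site of
#'   `subtype` instead.
#' @return A `distance_set` of kind `nearest`.
#' @export
to_4mc_distances <- function(sample, subtype = c("O6mA", "M6mA"), per_4mc = FALSE) {
  subtype <- match.arg(subtype)
  a_pos <- class_positions(sample, subtype)
  c_pos <- class_positions(sample, "4mC")
  if (per_4mc) {
    if (length(a_pos) == 0L) stop("no ", subtype, " sites in sample")
    nearest_cross_distances(c_pos, a_pos, from_class = "4mC", to_class = subtype)
  } else {
    if (length(c_pos) == 0L) stop("no 4mC sites in sample")
    nearest_cross_distances(a_pos, c_pos, from_class = subtype, to_class = "4mC")
  }
}
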