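#' Configuration for the cascade-methylome generator
#'
#' The generator realizes the inferred methylation cascade as a concrete
#' stochastic process: motif targets become M-6mA; each M-6mA anchors a
#' Poisson number of O-6mA at geometrically-distributed offsets; each O-6mA
#' seeds a 4mC on a nearby cytosine; and further 4mC accumulate next to
#' existing 4mC at gaps drawn from a power law with exponent
#' `cascade_exponent`, capped at `cascade_cap` bp — so a cytosine close to
#' an existing 4mC is far more likely to become methylated than a distant
#' one, and the binned frequency of adjacent-4mC distances decays as
#' `x^b`. Every distributional choice here (Poisson counts, geometric
#' offsets, the discrete seed-offset law, the gap law and its cap) is a
#' modeling choice of this package, not an observation.
#'
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param genome_length Genome length in bp (default 1e6).
#' @param gc_fraction GC fraction of the random background (default 0.61,
#'   a high-GC deltaproteobacterial genome).
#' @param topology `"circular"` or `"linear"`.
#' @param motif A [motif_spec()] (default GTACAG, target offset 4).
#' @param n_planted_motifs Motif copies planted in the background (default
#'   400).
#' @param o_per_m Mean O-6mA anchored per M-6mA (Poisson; default 1.7, so
#'   M-6mA make up ~37% of all 6mA).
#' @param o_offset_scale Scale (bp) of the symmetric geometric offset law
#'   for O-6mA placement around its anchor M-6mA (default 200).
#' @param m_methylation_prob Probability that a motif target is methylated
#'   (default 1: every motif occurrence carries M-6mA).
#' @param seed_4mc_prob Probability that an O-6mA seeds a 4mC (default 0.9).
#' @param seed_4mc_p1 Mass of the seed-offset law at 1 bp (default 0.25);
#'   the remainder is a truncated geometric over 2-10 bp.
#' @param seed_4mc_geom_p Success parameter of that truncated geometric
#'   (default 0.4).
#' @param n_4mc_multiplier Total 4mC target as a multiple of the 6mA count
#'   (default 20, the observed 4mC:6mA abundance ratio); overridden by
#'   `n_4mc_target` when given.
#' @param n_4mc_target Absolute 4mC target, or `NULL`.
#' @param cascade_exponent Power-law exponent `b_true` of the 4mC gap law
#'   (< 0; default -1.2).
#' @param cascade_cap Distance cap of the gap law in bp (default 250).
#' @param retention_rho Per-site retention probability of O-6mA and 4mC
#'   across conditions (default 0.65, so the four-condition intersection
#'   fraction is roughly `rho^3` ~ 0.27).
#' @param n_genes,gene_length_range,gene_gap_mean Annotation tiling
#'   parameters.
#' @param n_deg_base DEGs per unit condition intensity (default 20).
#' @param deg_effect_sd Spread of DEG log2 fold changes (default 2).
#' @param max_retries Collision-retry bound for site placement.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             genome_length = 1e6L,
                             gc_fraction = 0.61,
                             topology = "circular",
                             motif = motif_spec(),
                             n_planted_motifs = 400L,
                             o_per_m = 1.7,
                             o_offset_scale = 200,
                             m_methylation_prob = 1.0,
                             seed_4mc_prob = 0.9,
                             seed_4mc_p1 = 0.25,
                             seed_4mc_geom_p = 0.4,
                             n_4mc_multiplier = 20,
                             n_4mc_target = NULL,
                             cascade_exponent = -1.2,
                             cascade_cap = 250L,
                             retention_rho = 0.65,
                             n_genes = 900L,
                             gene_length_range = c(300L, 1500L),
                             gene_gap_mean = 80,
                             n_deg_base = 20L,
                             deg_effect_sd = 2,
                             max_retries = 200L) {
  stopifnot(gc_fraction > 0, gc_fraction < 1,
            m_methylation_prob >= 0, m_methylation_prob <= 1,
            seed_4mc_prob >= 0, seed_4mc_prob <= 1,
            retention_rho >= 0, retention_rho <= 1,
            cascade_exponent < 0)
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         gc_fraction = gc_fraction, topology = topology, motif = motif,
         n_planted_motifs = as.integer(n_planted_motifs), o_per_m = o_per_m,
         o_offset_scale = o_offset_scale,
         m_methylation_prob = m_methylation_prob,
         seed_4mc_prob = seed_4mc_prob, seed_4mc_p1 = seed_4mc_p1,
         seed_4mc_geom_p = seed_4mc_geom_p,
         n_4mc_multiplier = n_4mc_multiplier, n_4mc_target = n_4mc_target,
         cascade_exponent = cascade_exponent,
         cascade_cap = as.integer(cascade_cap),
         retention_rho = retention_rho,
         n_genes = as.integer(n_genes),
         gene_length_range = as.integer(gene_length_range),
         gene_gap_mean = gene_gap_mean,
         n_deg_base = as.integer(n_deg_base), deg_effect_sd = deg_effect_sd,
         max_retries = as.integer(max_retries)),
    class = "synthetic_config"
  )
}

# deterministic per-stage sub-seed (kept below 2^31 - 1; the multiply is
# exact in double precision since |master| * 48271 < 2^53)
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 48271 + stage) %% 2147483629)
}

#' Generate a random genome with a controlled number of motif copies
#'
#' Background bases are i.i.d. at the configured GC fraction; exactly
#' `n_planted_motifs` non-overlapping motif copies (random strand) are then
#' written in at uniform positions. Chance occurrences arising in the
#' background are scrubbed by point mutation, so the motif count is a
#' controlled parameter of the simulation: a scan finds exactly the planted
#' copies. Deterministic given the config seed.
#'
#' @param config A `synthetic_config`.
#' @return A `genome_seq`.
#' @export
generate_genome <- function(config) {
  L <- config$genome_length
  m <- nchar(config$motif$sequence)
  if (config$n_planted_motifs * m > L / 2) stop("infeasible motif planting")
  set.seed(derive_seed(config$seed, 1L))
  gc <- config$gc_fraction
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  occupied <- rep(FALSE, L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(config$motif$sequence)))
  motif_chars <- strsplit(config$motif$sequence, "", fixed = TRUE)[[1]]
  rc_chars <- strsplit(rc, "", fixed = TRUE)[[1]]
  planted <- 0L
  tries <- 0L
  planted_lo <- integer(config$n_planted_motifs)
  while (planted < config$n_planted_motifs) {
    tries <- tries + 1L
    if (tries > 100L * config$n_planted_motifs) stop("infeasible motif planting")
    s <- sample.int(L - m + 1L, 1L)
    win <- s:(s + m - 1L)
    if (any(occupied[win])) next
    chars[win] <- if (stats::runif(1) < 0.5) motif_chars else rc_chars
    occupied[win] <- TRUE
    planted <- planted + 1L
    planted_lo[planted] <- s
  }

  # scrub chance occurrences: mutate one free base inside each until only
  # the planted copies remain
  genome <- new_genome_seq("synthetic_contig", paste(chars, collapse = ""),
                           topology = config$topology)
  for (round in 1:20) {
    occ <- scan_motif(genome, config$motif)
    lo_all <- ifelse(occ$strand == "+", occ$start, occ$start - m + 1L)
    lo <- lo_all[!(lo_all %in% planted_lo)]
    if (length(lo) == 0L) break
    for (i in seq_along(lo)) {
      win <- ((lo[i] - 1L + 0:(m - 1L)) %% L) + 1L
      free <- win[!occupied[win]]
      if (length(free) == 0L) next  # wedged between planted copies; rare
      p <- free[sample.int(length(free), 1L)]
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    genome <- new_genome_seq("synthetic_contig", paste(chars, collapse = ""),
                             topology = config$topology)
  }
  genome
}

# truncated geometric over 2..10 bp plus a point mass at 1 bp
draw_seed_offsets <- function(n, config) {
  support <- 2:10
  w <- (1 - config$seed_4mc_geom_p)^(support - 2)
  pm <- c(config$seed_4mc_p1, (1 - config$seed_4mc_p1) * w / sum(w))
  sample(c(1L, support), n, replace = TRUE, prob = pm)
}

# Vectorized snap-to-nearest-free-base: for each target coordinate, picks
# the nearest unoccupied candidate base within a rank window of +/-4 around
# the insertion point (ties break leftward), marks it used and returns the
# chosen candidate indices (NA when the whole window is occupied —
# callers redraw those). Duplicate picks within one batch keep the first.
place_batch <- function(st, kind = c("aden", "cyt"), targets) {
  kind <- match.arg(kind)
  pos <- if (kind == "aden") st$aden_pos else st$cyt_pos
  used <- if (kind == "aden") st$aden_used else st$cyt_used
  n <- length(pos)
  W <- length(targets)
  if (W == 0L) return(integer(0))
  idx0 <- findInterval(targets, pos)
  offs <- c(-3L, -2L, -1L, 0L, 1L, 2L, 3L, 4L)
  cand <- outer(idx0, offs, "+")
  valid <- cand >= 1L & cand <= n
  candc <- pmin(pmax(cand, 1L), n)
  dist <- abs(matrix(pos[candc], W, 8L) - targets)
  dist[!valid] <- Inf
  dist[matrix(used[candc], W, 8L)] <- Inf
  pick <- max.col(-dist, ties.method = "first")
  sel <- cbind(seq_len(W), pick)
  chosen <- candc[sel]
  chosen[!is.finite(dist[sel])] <- NA_integer_
  chosen[duplicated(chosen) & !is.na(chosen)] <- NA_integer_
  got <- chosen[!is.na(chosen)]
  if (kind == "aden") st$aden_used[got] <- TRUE else st$cyt_used[got] <- TRUE
  chosen
}

#' Generate one cascade-structured methylome
#'
#' Runs the four cascade stages against a genome (see
#' [synthetic_config()]). All emitted sites carry `qv = 150`,
#' `coverage = 50`, so they pass the default read filter. Sites are returned
#' unclassified; [classify_6ma()] recovers the M/O split.
#'
#' @param genome A `genome_seq` containing at least one motif occurrence.
#' @param config A `synthetic_config`.
#' @param seed Seed for this sample (defaults to the config seed).
#' @param sample_id,condition Labels for the output sample.
#' @return A `methylome_sample`.
#' @export
generate_methylome_cascade <- function(genome, config, seed = config$seed,
                                       sample_id = "synthetic",
                                       condition = sample_id) {
  occ <- scan_motif(genome, config$motif)
  if (nrow(occ) == 0L) stop("genome contains no motif occurrence")
  st <- cascade_state_new(genome, config)
  st <- cascade_stage1(st, occ, config, derive_seed(seed, 11L))
  st <- cascade_stage2(st, config, derive_seed(seed, 12L),
                       n_new = NULL, anchors = NULL)
  st <- cascade_stage3(st, config, derive_seed(seed, 13L),
                       o_subset = seq_along(st$o_pos))
  n6 <- length(st$m_pos) + length(st$o_pos)
  target <- if (!is.null(config$n_4mc_target)) config$n_4mc_target else
    as.integer(round(config$n_4mc_multiplier * n6))
  st <- cascade_stage4(st, config, derive_seed(seed, 14L), target)
  cascade_assemble(st, genome, sample_id, condition)
}

# ---- internal cascade machinery ----------------------------------------

# Mutable generator state held in an environment: positions of modifiable
# bases, occupancy flags, the capped distance-to-nearest-4mC array over
# cytosine candidates, and the growing site lists. An environment (rather
# than a list) keeps the large occupancy/distance vectors modifiable in
# place across the ~10^4 site insertions.
cascade_state_new <- function(genome, config) {
  raw <- charToRaw(genome$sequence)
  aden_pos <- which(raw == charToRaw("A") | raw == charToRaw("T"))
  cyt_pos <- which(raw == charToRaw("C") | raw == charToRaw("G"))
  if (length(aden_pos) == 0L || length(cyt_pos) == 0L) {
    stop("genome has no adenines or no cytosines")
  }
  st <- new.env(parent = emptyenv())
  st$raw <- raw
  st$aden_pos <- aden_pos
  st$aden_used <- rep(FALSE, length(aden_pos))
  st$cyt_pos <- cyt_pos
  st$cyt_used <- rep(FALSE, length(cyt_pos))
  st$m_pos <- integer(0)
  st$o_pos <- integer(0)
  st$c_buf <- integer(65536L)   # preallocated 4mC position buffer
  st$n_c <- 0L
  st
}

cascade_c_pos <- function(st) st$c_buf[seq_len(st$n_c)]

cascade_stage1 <- function(st, occ, config, stage_seed) {
  set.seed(stage_seed)
  keep <- stats::runif(nrow(occ)) < config$m_methylation_prob
  m_pos <- sort(unique(occ$target_position[keep]))
  st$m_pos <- m_pos
  st$aden_used[match(m_pos, st$aden_pos)] <- TRUE
  invisible(st)
}

# place O-6mA around anchors; with anchors=NULL draws Poisson(o_per_m) per M,
# otherwise adds exactly n_new sites anchored at uniformly chosen M sites
cascade_stage2 <- function(st, config, stage_seed, n_new = NULL, anchors = NULL) {
  set.seed(stage_seed)
  if (is.null(anchors)) {
    counts <- stats::rpois(length(st$m_pos), config$o_per_m)
    anchors <- rep(st$m_pos, counts)
  } else if (!is.null(n_new)) {
    anchors <- if (n_new > 0L) st$m_pos[sample.int(length(st$m_pos), n_new, replace = TRUE)]
               else integer(0)
  }
  new_o <- integer(0)
  pending <- anchors
  for (round in seq_len(config$max_retries)) {
    if (length(pending) == 0L) break
    mag <- stats::rgeom(length(pending), 1 / config$o_offset_scale) + 1L
    sgn <- sample(c(-1L, 1L), length(pending), replace = TRUE)
    chosen <- place_batch(st, "aden", pending + sgn * mag)
    new_o <- c(new_o, st$aden_pos[chosen[!is.na(chosen)]])
    pending <- pending[is.na(chosen)]
  }
  if (length(pending) > 0L) {
    stop("could not place O-6mA after ", config$max_retries, " retries")
  }
  st$o_pos <- sort(c(st$o_pos, new_o))
  invisible(st)
}

# seed 4mC next to a subset of O-6mA sites (indices into st$o_pos)
cascade_stage3 <- function(st, config, stage_seed, o_subset) {
  set.seed(stage_seed)
  seeded <- o_subset[stats::runif(length(o_subset)) < config$seed_4mc_prob]
  pending <- st$o_pos[seeded]
  for (round in seq_len(config$max_retries)) {
    if (length(pending) == 0L) break
    delta <- draw_seed_offsets(length(pending), config)
    sgn <- sample(c(-1L, 1L), length(pending), replace = TRUE)
    chosen <- place_batch(st, "cyt", pending + sgn * delta)
    append_4mc(st, st$cyt_pos[chosen[!is.na(chosen)]])
    pending <- pending[is.na(chosen)]
  }
  if (length(pending) > 0L) {
    stop("could not place seed 4mC after ", config$max_retries, " retries")
  }
  invisible(st)
}

# append already-placed 4mC positions to the growing buffer
append_4mc <- function(st, positions) {
  k <- length(positions)
  if (k == 0L) return(invisible(st))
  while (st$n_c + k > length(st$c_buf)) {
    st$c_buf <- c(st$c_buf, integer(length(st$c_buf)))
  }
  st$c_buf[st$n_c + seq_len(k)] <- positions
  st$n_c <- st$n_c + k
  invisible(st)
}

# draw inter-4mC gaps from the binned power law: bin k (midpoint m_k) with
# probability proportional to m_k^b, uniform within the bin, up to the cap
draw_gap_law <- function(n, config) {
  b <- config$cascade_exponent
  cap <- config$cascade_cap
  n_bins <- 25L
  width <- max(1L, cap %/% n_bins)
  mids <- seq_len(n_bins) * width - width / 2
  bin_prob <- mids^b / sum(mids^b)
  k <- sample.int(n_bins, n, replace = TRUE, prob = bin_prob)
  (k - 1L) * width + sample.int(width, n, replace = TRUE)
}

# top up the 4mC set with uniformly chosen free cytosines (used for the
# rare snapping collisions so class counts come out exact)
topup_4mc <- function(st, n_fill, config) {
  rounds <- 0L
  while (n_fill > 0L) {
    rounds <- rounds + 1L
    if (rounds > config$max_retries) stop("could not top up 4mC count")
    free <- which(!st$cyt_used)
    if (length(free) < n_fill) stop("unreachable n_4mc_target: cytosines exhausted")
    pick <- free[sample.int(length(free), n_fill)]
    st$cyt_used[pick] <- TRUE
    append_4mc(st, st$cyt_pos[pick])
    n_fill <- 0L
  }
  invisible(st)
}

# Grow 4mC as a renewal chain: successive sites are laid along the genome
# with gaps drawn from the binned power law — each new 4mC uses the
# previous one as its reference — and the genome length not consumed by
# those short gaps is spent in a small number of long inter-cluster voids
# (> cap, so they fall outside the binned histogram). Chain coordinates
# are snapped to the nearest unmodified cytosine. By construction the
# binned frequency of adjacent-4mC distances decays as mid^b, which is the
# observable the allometric fit measures; snapping and the interleaved
# O-6mA-adjacent seed 4mC perturb it mildly (quantified in the tests).
cascade_stage4 <- function(st, config, stage_seed, n_target) {
  set.seed(stage_seed)
  cap <- config$cascade_cap
  L <- length(st$raw)
  if (n_target > length(st$cyt_pos)) {
    stop("unreachable n_4mc_target: more than available cytosines")
  }
  n_new <- n_target - st$n_c
  if (n_new <= 0L) return(invisible(st))
  gaps <- draw_gap_law(n_new, config)
  leftover <- L - sum(gaps)
  if (leftover < 0L) {
    stop("gap law cannot fit n_4mc_target in this genome (density too high)")
  }
  n_void <- max(1L, min(n_new %/% 10L, floor(leftover / (2 * cap))))
  if (leftover > cap && n_void > 0L) {
    stick <- stats::rexp(n_void)
    voids <- cap + floor(stick / sum(stick) * (leftover - n_void * cap))
    at <- sample.int(n_new, n_void)
    gaps[at] <- gaps[at] + voids   # a void and a short gap merge; still > cap
  }
  start <- sample.int(L, 1L)
  coords <- ((start + cumsum(as.numeric(gaps)) - 1) %% L) + 1
  chosen <- place_batch(st, "cyt", sort(coords))
  append_4mc(st, st$cyt_pos[chosen[!is.na(chosen)]])
  topup_4mc(st, n_target - st$n_c, config)
  invisible(st)
}

# Rebuild thinned 4mC runs for a derived condition: for each maximal run of
# removed sites between two retained neighbours, redraw the run with fresh
# power-law gaps from the left neighbour (falling back to uniform placement
# when the redrawn run does not fit the available window)
cascade_regrow_4mc <- function(st, kept, runs, n_fill, config, stage_seed) {
  set.seed(stage_seed)
  if (n_fill <= 0L || length(runs$k) == 0L) {
    return(topup_4mc(st, max(n_fill, 0L), config))
  }
  # shed slots at random when stage-3 seeding already used part of the budget
  k <- runs$k
  excess <- sum(k) - n_fill
  while (excess > 0L) {
    i <- sample(rep.int(seq_along(k), k), 1L)
    k[i] <- k[i] - 1L
    excess <- excess - 1L
  }
  targets <- numeric(0)
  for (i in seq_along(k)) {
    if (k[i] == 0L) next
    G <- runs$width[i]
    pos <- NULL
    for (try in 1:10) {
      g <- draw_gap_law(k[i], config)
      cand <- runs$left[i] + cumsum(as.numeric(g))
      if (cand[k[i]] < runs$left[i] + G) { pos <- cand; break }
    }
    if (is.null(pos)) {
      pos <- runs$left[i] + sort(sample.int(max(G - 1L, k[i]), k[i]))
    }
    targets <- c(targets, pos)
  }
  targets <- ((targets - 1) %% length(st$raw)) + 1
  chosen <- place_batch(st, "cyt", sort(targets))
  append_4mc(st, st$cyt_pos[chosen[!is.na(chosen)]])
  topup_4mc(st, n_fill - sum(!is.na(chosen)), config)
  invisible(st)
}

cascade_assemble <- function(st, genome, sample_id, condition) {
  pos6 <- sort(c(st$m_pos, st$o_pos))
  base6 <- rawToChar(st$raw[pos6], multiple = TRUE)
  pos4 <- sort(cascade_c_pos(st))
  base4 <- rawToChar(st$raw[pos4], multiple = TRUE)
  sites <- data.frame(
    contig = genome$contig_id,
    position = c(pos6, pos4),
    strand = c(ifelse(base6 == "A", "+", "-"), ifelse(base4 == "C", "+", "-")),
    mod_type = rep(c("6mA", "4mC"), c(length(pos6), length(pos4))),
    qv = 150L,
    coverage = 50L,
    stringsAsFactors = FALSE
  )
  new_methylome_sample(sites, sample_id = sample_id, condition = condition,
                       genome = genome)
}

#' Generate a family of condition methylomes with partial site retention
#'
#' The first condition is generated fresh. Every subsequent condition keeps
#' all M-6mA (their genomic positions are fixed across conditions),
#' independently retains each O-6mA and each 4mC with probability
#' `retention_rho`, and regrows back to the first condition's class counts
#' through the cascade stages. Per-condition seeds derive deterministically
#' from the master seed.
#'
#' @param genome A `genome_seq`.
#' @param config A `synthetic_config`.
#' @param n_conditions Number of conditions (default 4).
#' @param condition_labels Labels (default `control`, `1G`, `10G`, `100G`).
#' @return Named list of `methylome_sample` objects.
#' @export
generate_sample_family <- function(genome, config, n_conditions = 4L,
                                   condition_labels = c("control", "1G", "10G", "100G")) {
  n_conditions <- as.integer(n_conditions)
  if (length(condition_labels) < n_conditions) {
    condition_labels <- c(condition_labels,
                          paste0("cond", seq_len(n_conditions)))[seq_len(n_conditions)]
  }
  occ <- scan_motif(genome, config$motif)
  if (nrow(occ) == 0L) stop("genome contains no motif occurrence")

  base_seed <- derive_seed(config$seed, 100L)
  st1 <- cascade_state_new(genome, config)
  st1 <- cascade_stage1(st1, occ, config, derive_seed(base_seed, 11L))
  st1 <- cascade_stage2(st1, config, derive_seed(base_seed, 12L))
  st1 <- cascade_stage3(st1, config, derive_seed(base_seed, 13L),
                        o_subset = seq_along(st1$o_pos))
  n6 <- length(st1$m_pos) + length(st1$o_pos)
  target4 <- if (!is.null(config$n_4mc_target)) config$n_4mc_target else
    as.integer(round(config$n_4mc_multiplier * n6))
  st1 <- cascade_stage4(st1, config, derive_seed(base_seed, 14L), target4)
  n_o_target <- length(st1$o_pos)

  out <- vector("list", n_conditions)
  names(out) <- condition_labels[seq_len(n_conditions)]
  out[[1]] <- cascade_assemble(st1, genome, condition_labels[1], condition_labels[1])

  for (j in seq_len(n_conditions - 1L) + 1L) {
    sj <- derive_seed(config$seed, 100L + j)
    set.seed(derive_seed(sj, 10L))
    st <- cascade_state_new(genome, config)
    # M-6mA fixed across conditions
    st$m_pos <- st1$m_pos
    st$aden_used[match(st$m_pos, st$aden_pos)] <- TRUE
    # retain O-6mA with probability rho
    keep_o <- st1$o_pos[stats::runif(length(st1$o_pos)) < config$retention_rho]
    st$o_pos <- keep_o
    st$aden_used[match(keep_o, st$aden_pos)] <- TRUE
    # retain 4mC with probability rho; remember where the removed runs were
    c1 <- sort(cascade_c_pos(st1))
    keep_mask <- stats::runif(length(c1)) < config$retention_rho
    keep_c <- c1[keep_mask]
    runs <- thin_runs(c1, keep_mask, genome$length)
    st$cyt_used[match(keep_c, st$cyt_pos)] <- TRUE
    append_4mc(st, keep_c)
    # regrow O to the original count, anchored at random M sites
    n_new_o <- n_o_target - length(keep_o)
    st <- cascade_stage2(st, config, derive_seed(sj, 12L),
                         n_new = n_new_o, anchors = NA)
    # seed 4mC only from the regrown O sites
    new_idx <- which(!(st$o_pos %in% keep_o))
    st <- cascade_stage3(st, config, derive_seed(sj, 13L), o_subset = new_idx)
    # refill the thinned runs back to the original 4mC count
    st <- cascade_regrow_4mc(st, keep_c, runs, target4 - st$n_c, config,
                             derive_seed(sj, 14L))
    out[[j]] <- cascade_assemble(st, genome, condition_labels[j], condition_labels[j])
  }
  out
}

# Maximal runs of removed sites after thinning a sorted (circular) position
# set: each run is described by the retained left neighbour, the window
# width to the retained right neighbour, and the number of removed sites.
thin_runs <- function(positions, keep_mask, L) {
  n <- length(positions)
  if (all(keep_mask)) return(list(left = numeric(0), width = numeric(0), k = integer(0)))
  if (!any(keep_mask)) return(list(left = positions[1], width = L, k = n))
  i0 <- which(keep_mask)[1]
  rot <- c(i0:n, seq_len(i0 - 1L))
  m <- keep_mask[rot]
  p <- as.numeric(positions[rot])
  p[rot < i0] <- p[rot < i0] + L   # unwrap so coordinates increase
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(!r$values)
  left <- p[starts[idx] - 1L]
  right <- ifelse(ends[idx] == n, p[1] + L, p[pmin(ends[idx] + 1L, n)])
  list(left = left, width = right - left, k = ends[idx] - starts[idx] + 1L)
}

#' Generate a gene annotation and matched DEG tables
#'
#' Tiles the genome with non-overlapping genes of random strand separated by
#' random intergenic gaps, then builds one DEG table per contrast: the DEG
#' count grows proportionally with the condition intensity (the contrast
#' against a stronger exposure has more DEGs), differentially expressed
#' genes get adjusted p below 0.05 and a log2 fold change drawn from the
#' configured effect law, all other genes are non-significant.
#'
#' @param genome A `genome_seq`.
#' @param config A `synthetic_config`.
#' @param intensities Named integer vector: contrast label -> intensity
#'   (default `c("1G" = 1, "10G" = 2, "100G" = 3)`).
#' @return List with `features` (annotation data frame) and `deg_tables`
#'   (named list of DEG data frames).
#' @export
generate_annotation_and_degs <- function(genome, config,
                                         intensities = c("1G" = 1L, "10G" = 2L, "100G" = 3L)) {
  set.seed(derive_seed(config$seed, 300L))
  L <- genome$length
  rng <- config$gene_length_range
  if (config$n_genes * mean(rng) > L) stop("infeasible tiling: genes do not fit")
  starts <- integer(config$n_genes)
  ends <- integer(config$n_genes)
  cursor <- 1L + stats::rgeom(1L, 1 / config$gene_gap_mean)
  for (i in seq_len(config$n_genes)) {
    len <- sample(rng[1]:rng[2], 1L)
    if (cursor + len - 1L > L) stop("infeasible tiling: ran out of genome at gene ", i)
    starts[i] <- cursor
    ends[i] <- cursor + len - 1L
    cursor <- ends[i] + 1L + 20L + stats::rgeom(1L, 1 / config$gene_gap_mean)
  }
  features <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
    contig = genome$contig_id,
    start = starts, end = ends,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )

  deg_tables <- lapply(seq_along(intensities), function(k) {
    set.seed(derive_seed(config$seed, 300L + k))
    n_deg <- min(config$n_deg_base * intensities[k], config$n_genes)
    deg_idx <- sample.int(config$n_genes, n_deg)
    log2fc <- stats::rnorm(config$n_genes, 0, 0.3)
    padj <- stats::runif(config$n_genes, 0.05, 1)
    sgn <- sample(c(-1, 1), n_deg, replace = TRUE)
    log2fc[deg_idx] <- sgn * (abs(stats::rnorm(n_deg, 0, config$deg_effect_sd)) + 0.5)
    padj[deg_idx] <- stats::runif(n_deg, 0, 0.049)
    deg_table(data.frame(
      gene_id = features$gene_id,
      log2fc = log2fc,
      padj = padj,
      stringsAsFactors = FALSE
    ))
  })
  names(deg_tables) <- paste0("control_vs_", names(intensities))
  list(features = features, deg_tables = deg_tables)
}

#' Materialize a complete synthetic test bundle on disk
#'
#' Writes the genome FASTA, one methylome TSV (and one basemods-style GFF3)
#' per condition, the annotation TSV, one DEG TSV per contrast, and a JSON
#' echo of the configuration. Everything is readable back through the
#' package's readers.
#'
#' @param dir Output directory (created if needed).
#' @param config A `synthetic_config`.
#' @param n_conditions Number of methylome conditions.
#' @return Named list of written paths.
#' @export
write_fixture_bundle <- function(dir, config, n_conditions = 4L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(config)
  samples <- generate_sample_family(genome, config, n_conditions = n_conditions)
  ann <- generate_annotation_and_degs(genome, config)
  paths <- list(genome = file.path(dir, "genome.fasta"))
  write_genome(genome, paths$genome)
  for (nm in names(samples)) {
    p_tsv <- file.path(dir, paste0("methylome_", nm, ".tsv"))
    write_methylome(samples[[nm]], p_tsv, format = "tsv")
    p_gff <- file.path(dir, paste0("methylome_", nm, ".gff3"))
    write_methylome(samples[[nm]], p_gff, format = "basemods_gff3")
    paths[[paste0("methylome_", nm)]] <- p_tsv
    paths[[paste0("methylome_gff3_", nm)]] <- p_gff
  }
  paths$annotation <- file.path(dir, "annotation.tsv")
  write_annotation(ann$features, paths$annotation)
  for (nm in names(ann$deg_tables)) {
    p <- file.path(dir, paste0("deg_", nm, ".tsv"))
    write_deg_table(ann$deg_tables[[nm]], p)
    paths[[paste0("deg_", nm)]] <- p
  }
  paths$config <- file.path(dir, "config.json")
  cfg <- config
  cfg$motif <- unclass(cfg$motif)
  jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
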