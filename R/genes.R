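#' Strand-aware upstream window of a gene
#'
#' The window of `length` bp immediately 5' of the gene on its own strand,
#' excluding the gene body: a '+' gene starting at `s` gets `[s-length,
#' s-1]`; a '-' gene ending at `e` gets `[e+1, e+length]`. Linear genomes
#' clip the window at the chromosome ends (the achieved length is recorded);
#' circular genomes wrap, in which case the window may come back as two
#' forward-coordinate intervals.
#'
#' @param feature One-row annotation data frame (or list) with `start`,
#'   `end`, `strand`.
#' @param length Window length in bp (default 200).
#' @param genome A `genome_seq` (supplies length and topology).
#' @return Data frame of intervals (`start`, `end`), attribute
#'   `achieved_length`.
#' @export
upstream_region <- function(feature, length = 200L, genome) {
  length <- as.integer(length)
  L <- genome$length
  if (feature$strand == "+") {
    lo <- feature$start - length
    hi <- feature$start - 1L
  } else {
    lo <- feature$end + 1L
    hi <- feature$end + length
  }
  if (genome$topology == "linear") {
    lo2 <- max(lo, 1L)
    hi2 <- min(hi, L)
    if (hi2 < lo2) {
      out <- data.frame(start = integer(0), end = integer(0))
      attr(out, "achieved_length") <- 0L
      return(out)
    }
    out <- data.frame(start = lo2, end = hi2)
    attr(out, "achieved_length") <- hi2 - lo2 + 1L
    return(out)
  }
  # circular: wrap modulo L; window length min(length, L)
  if (hi - lo + 1L >= L) {
    out <- data.frame(start = 1L, end = L)
    attr(out, "achieved_length") <- L
    return(out)
  }
  wrap <- function(x) ((x - 1L) %% L) + 1L
  lo_w <- wrap(lo)
  hi_w <- wrap(hi)
  if (lo_w <= hi_w) {
    out <- data.frame(start = lo_w, end = hi_w)
  } else {
    out <- data.frame(start = c(lo_w, 1L), end = c(L, hi_w))
  }
  attr(out, "achieved_length") <- hi - lo + 1L
  out
}

# count of modifiable bases (both strands) inside forward intervals
interval_modifiable_bases <- function(genome, intervals, mod_type) {
  letters <- if (mod_type == "4mC") c("C", "G") else c("A", "T")
  total <- 0L
  for (i in seq_len(nrow(intervals))) {
    seg <- substring(genome$sequence, intervals$start[i], intervals$end[i])
    raw <- charToRaw(seg)
    total <- total + sum(raw == charToRaw(letters[1]) | raw == charToRaw(letters[2]))
  }
  total
}

#' Per-feature methylation levels
#'
#' For each gene (or its upstream window), the methylation level of a site
#' class: modified sites whose forward coordinate falls in the region
#' (either strand) divided by the region's modifiable bases (C on both
#' strands for 4mC; A on both strands for the 6mA classes). A site inside
#' two overlapping genes counts in both. Regions with no modifiable base
#' get `level = NA` and are flagged via `level_defined`.
#'
#' @param sample A `methylome_sample` (classified if `mod_class` is a 6mA
#'   subtype).
#' @param features Annotation data frame.
#' @param genome A `genome_seq`.
#' @param region `"body"` or `"upstream200"`.
#' @param mod_class `"4mC"`, `"6mA"`, `"M6mA"` or `"O6mA"`.
#' @param upstream_length Window length used when `region = "upstream200"`.
#' @return Data frame: `gene_id`, `region`, `mod_class`, `site_count`,
#'   `modifiable_bases`, `level`, `level_defined`.
#' @export
feature_methylation <- function(sample, features, genome,
                                region = c("body", "upstream200"),
                                mod_class = c("4mC", "6mA", "M6mA", "O6mA"),
                                upstream_length = 200L) {
  region <- match.arg(region)
  mod_class <- match.arg(mod_class)
  mod_type <- if (mod_class == "4mC") "4mC" else "6mA"
  pos <- class_positions(sample, mod_class)
  n <- nrow(features)
  site_count <- integer(n)
  bases <- integer(n)
  for (i in seq_len(n)) {
    f <- features[i, , drop = FALSE]
    intervals <- if (region == "body") {
      data.frame(start = f$start, end = f$end)
    } else {
      upstream_region(f, length = upstream_length, genome = genome)
    }
    if (any(intervals$end > genome$length) || any(intervals$start < 1L)) {
      stop("region outside genome for gene ", f$gene_id)
    }
    cnt <- 0L
    for (j in seq_len(nrow(intervals))) {
      cnt <- cnt + sum(pos >= intervals$start[j] & pos <= intervals$end[j])
    }
    site_count[i] <- cnt
    bases[i] <- interval_modifiable_bases(genome, intervals, mod_type)
  }
  data.frame(
    gene_id = features$gene_id,
    region = rep(region, n),
    mod_class = rep(mod_class, n),
    site_count = site_count,
    modifiable_bases = bases,
    level = ifelse(bases == 0L, NA_real_, site_count / bases),
    level_defined = bases > 0L,
    stringsAsFactors = FALSE
  )
}

#' Genome-wide methylation level
#'
#' Modified sites per modifiable base over the whole genome — the same
#' units as [feature_methylation()] levels, so gene-versus-genome
#' comparisons are length-independent. Equals
#' [methylation_percentage()] / 100 for the plain mod types.
#'
#' @param sample A `methylome_sample`.
#' @param composition A `base_composition`.
#' @param mod_class `"4mC"`, `"6mA"`, `"M6mA"` or `"O6mA"`.
#' @return Level in `[0, 1]`.
#' @export
genome_level <- function(sample, composition, mod_class = c("4mC", "6mA", "M6mA", "O6mA")) {
  mod_class <- match.arg(mod_class)
  denom <- if (mod_class == "4mC") composition$cytosines_both else composition$adenines_both
  if (denom == 0L) stop("zero denominator")
  length(class_positions(sample, mod_class)) / denom
}

#' Compare DEG methylation levels against the genome-wide level
#'
#' For each direction (up/down), counts differentially expressed genes whose
#' feature methylation level is below the genome-wide level, and those with
#' no modification at all.
#'
#' @param deg_records DEG data frame with `gene_id` and `direction`.
#' @param feature_levels Output of [feature_methylation()] covering every
#'   DEG gene.
#' @param genome_lvl Genome-wide level from [genome_level()].
#' @return Data frame with one row per direction: `direction`, `n_total`,
#'   `n_lower_than_genome`, `n_zero`, `fraction_lower`, `fraction_zero`.
#' @export
categorize_degs <- function(deg_records, feature_levels, genome_lvl) {
  degs <- deg_records[deg_records$direction %in% c("up", "down"), , drop = FALSE]
  missing_ids <- setdiff(degs$gene_id, feature_levels$gene_id)
  if (length(missing_ids) > 0L) {
    stop("DEG gene(s) missing from annotation/levels: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  lvl <- feature_levels$level[match(degs$gene_id, feature_levels$gene_id)]
  if (anyNA(lvl)) stop("undefined methylation level for some DEG genes")
  out <- lapply(c("down", "up"), function(dir) {
    l <- lvl[degs$direction == dir]
    n <- length(l)
    data.frame(
      direction = dir,
      n_total = n,
      n_lower_than_genome = sum(l < genome_lvl),
      n_zero = sum(l == 0),
      fraction_lower = if (n == 0L) NA_real_ else sum(l < genome_lvl) / n,
      fraction_zero = if (n == 0L) NA_real_ else sum(l == 0) / n,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Pearson correlation with two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from the t
#' transform with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with non-zero
#'   variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-gene methylation levels and DEG status for selected genes
#'
#' Joins each requested gene's feature methylation level in every sample
#' with its differential-expression call in every contrast. Intended for
#' spot reports on genes of interest (e.g. the two methyltransferase genes
#' of *G. sulfurreducens*, GSU0227 and GSU1244).
#'
#' @param samples Named list of `methylome_sample` objects.
#' @param features Annotation data frame.
#' @param genome A `genome_seq`.
#' @param deg_tables Named list of DEG data frames (one per contrast).
#' @param gene_ids Genes to report.
#' @param mod_class Site class for the levels (default `"4mC"`).
#' @return Data frame, one row per gene: level per sample (`level_<id>`)
#'   and direction per contrast (`deg_<contrast>`). Empty `gene_ids` give
#'   an empty table.
#' @export
methyltransferase_report <- function(samples, features, genome, deg_tables,
                                     gene_ids, mod_class = "4mC") {
  unknown <- setdiff(gene_ids, features$gene_id)
  if (length(unknown) > 0L) stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  sel <- features[match(gene_ids, features$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (nm in names(samples)) {
    fl <- feature_methylation(samples[[nm]], sel, genome,
                              region = "body", mod_class = mod_class)
    out[[paste0("level_", nm)]] <- fl$level[match(gene_ids, fl$gene_id)]
  }
  for (nm in names(deg_tables)) {
    dt <- deg_tables[[nm]]
    dir <- dt$direction[match(gene_ids, dt$gene_id)]
    out[[paste0("deg_", nm)]] <- ifelse(is.na(dir), "absent", dir)
  }
  out
}
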