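#' Cross-sample overlap of methylation sites
#'
#' Sites are identified by (contig, position, strand). For each sample the
#' shared fraction is the size of the all-sample intersection divided by
#' that sample's own site count (so "x% of this sample's sites are present
#' in all samples"); the union-denominator reading is available through the
#' pairwise Jaccard matrix and `intersection_all / union_all`.
#'
#' @param samples List of two or more `methylome_sample` objects called
#'   against the same genome.
#' @param mod_class `"4mC"`, `"6mA"`, `"M6mA"` or `"O6mA"` (subtypes
#'   require classified samples).
#' @return An `overlap_result`: `sample_ids`, `counts`, `intersection_all`,
#'   `union_all`, `fraction_shared_per_sample`, `jaccard` (matrix).
#' @export
site_overlap <- function(samples, mod_class = c("4mC", "6mA", "M6mA", "O6mA")) {
  mod_class <- match.arg(mod_class)
  if (length(samples) < 2L) stop("site_overlap needs at least 2 samples")
  keys <- lapply(samples, function(sm) {
    s <- sm$sites
    keep <- switch(mod_class,
      "4mC" = s$mod_type == "4mC",
      "6mA" = s$mod_type == "6mA",
      "M6mA" = s$mod_type == "6mA" & s$subtype == "M",
      "O6mA" = s$mod_type == "6mA" & s$subtype == "O"
    )
    if (mod_class %in% c("M6mA", "O6mA") &&
        any(s$subtype[s$mod_type == "6mA"] == "unset")) {
      stop("sample ", sm$sample_id, " not classified")
    }
    unique(paste(s$contig[keep], s$position[keep], s$strand[keep]))
  })
  ids <- unname(vapply(samples, function(sm) sm$sample_id, character(1)))
  counts <- unname(lengths(keys))
  empty <- counts == 0L
  if (any(empty)) {
    warning("empty ", mod_class, " class in sample(s): ",
            paste(ids[empty], collapse = ", "), "; shared fraction undefined there")
  }
  inter <- Reduce(intersect, keys)
  uni <- Reduce(union, keys)
  k <- length(samples)
  jac <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      u <- length(union(keys[[i]], keys[[j]]))
      jac[i, j] <- if (u == 0L) NA_real_ else
        length(intersect(keys[[i]], keys[[j]])) / u
    }
  }
  structure(
    list(
      sample_ids = ids,
      mod_class = mod_class,
      counts = counts,
      intersection_all = length(inter),
      union_all = length(uni),
      fraction_shared_per_sample = ifelse(counts == 0L, NA_real_,
                                          length(inter) / counts),
      jaccard = jac
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %s over %d samples: |intersection|=%d, |union|=%d\n",
              x$mod_class, length(x$sample_ids), x$intersection_all, x$union_all))
  cat("  shared fraction per sample:",
      paste(sprintf("%s=%.3f", x$sample_ids, x$fraction_shared_per_sample),
            collapse = ", "), "\n")
  invisible(x)
}

#' Multiset overlap of two distance sets
#'
#' The intersection counts each distance value with its minimum multiplicity
#' in the two sets: a value occurring 5 times in `a` and 3 times in `b`
#' contributes 3. This is the "same amount of each distance" comparison for
#' O-6mA-to-M-6mA spacing between conditions.
#'
#' @param a,b `distance_set` objects with identical contexts.
#' @return A `multiset_overlap`: sizes, `intersection_size`,
#'   `fraction_of_a`, `fraction_of_b`.
#' @export
distance_multiset_overlap <- function(a, b) {
  if (!identical(a$context, b$context)) {
    stop("distance sets have different contexts")
  }
  ta <- table(a$distances)
  tb <- table(b$distances)
  shared <- intersect(names(ta), names(tb))
  inter <- sum(pmin(as.integer(ta[shared]), as.integer(tb[shared])))
  na <- length(a$distances)
  nb <- length(b$distances)
  structure(
    list(
      size_a = na, size_b = nb, intersection_size = inter,
      fraction_of_a = if (na == 0L) NA_real_ else inter / na,
      fraction_of_b = if (nb == 0L) NA_real_ else inter / nb
    ),
    class = "multiset_overlap"
  )
}

#' Venn region counts for 2-4 named gene sets
#'
#' Counts the elements in every region of the Venn diagram. Regions are
#' keyed by the membership pattern, e.g. `"A&B"` for elements in sets A and
#' B but no other.
#'
#' @param sets Named list of 2-4 character vectors (gene ids; duplicates
#'   ignored).
#' @return A data frame with columns `region` and `count`, plus attribute
#'   `total` (= size of the union); regions with zero members included.
#' @export
gene_set_overlap <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L) stop("gene_set_overlap supports 2-4 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- Reduce(union, sets)
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- apply(membership, 1L, function(row) paste(names(sets)[row], collapse = "&"))
  all_patterns <- unlist(lapply(seq_len(k), function(m) {
    combn(names(sets), m, FUN = paste, collapse = "&")
  }))
  counts <- table(factor(patterns, levels = all_patterns))
  out <- data.frame(region = all_patterns, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- length(universe)
  out
}
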