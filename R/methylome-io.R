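#' Construct a methylome sample from a site table
#'
#' A methylome sample is a sorted, deduplicated collection of called modified
#' bases for one DNA sample (one exposure condition). All coordinates are
#' 1-based forward-strand positions of the modified base itself, for sites on
#' either strand, so cross-strand distance arithmetic is a plain difference.
#'
#' @param sites Data frame with columns `contig`, `position`, `strand`
#'   (`+`/`-`), `mod_type` (`4mC`/`6mA`), `qv`, `coverage` (both may be NA)
#'   and optionally `subtype` (`M`/`O`/`unset`, 6mA only).
#' @param sample_id Sample identifier.
#' @param condition Condition label (e.g. `control`, `1G`, `10G`, `100G`).
#' @param genome Optional `genome_seq`; when supplied, each site's reference
#'   base is checked (C for 4mC, A for 6mA, on the site's own strand).
#' @return A `methylome_sample` object.
#' @export
new_methylome_sample <- function(sites, sample_id, condition = sample_id, genome = NULL) {
  required <- c("contig", "position", "strand", "mod_type")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0L) {
    stop("site table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  sites$position <- as.integer(sites$position)
  if (anyNA(sites$position) || any(sites$position < 1L)) {
    stop("malformed coordinates: positions must be positive integers")
  }
  if (!all(sites$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(sites$mod_type %in% c("4mC", "6mA"))) {
    stop("unknown mod type: ", paste(setdiff(unique(sites$mod_type), c("4mC", "6mA")), collapse = ", "))
  }
  n_in <- nrow(sites)
  if (is.null(sites$qv)) sites$qv <- rep(NA_integer_, n_in)
  if (is.null(sites$coverage)) sites$coverage <- rep(NA_integer_, n_in)
  sites$qv <- as.integer(sites$qv)
  sites$coverage <- as.integer(sites$coverage)
  if (is.null(sites$subtype)) sites$subtype <- rep("unset", n_in)
  sites$subtype[sites$mod_type == "4mC"] <- "unset"

  # dedup on (contig, position, strand, mod_type), keeping the highest QV
  ord <- order(sites$contig, sites$position, sites$strand, sites$mod_type,
               -ifelse(is.na(sites$qv), -1L, sites$qv))
  sites <- sites[ord, , drop = FALSE]
  key <- paste(sites$contig, sites$position, sites$strand, sites$mod_type)
  sites <- sites[!duplicated(key), , drop = FALSE]
  ord <- order(sites$contig, sites$position, sites$strand)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL

  if (!is.null(genome)) {
    if (any(sites$position > genome$length)) stop("site position beyond genome length")
    base <- substring(genome$sequence, sites$position, sites$position)
    expect <- ifelse(sites$mod_type == "4mC",
                     ifelse(sites$strand == "+", "C", "G"),
                     ifelse(sites$strand == "+", "A", "T"))
    if (any(base != expect)) {
      n_bad <- sum(base != expect)
      stop(n_bad, " site(s) whose reference base does not match the modification type")
    }
  }

  structure(
    list(sample_id = sample_id, condition = condition, sites = sites),
    class = "methylome_sample"
  )
}

#' @export
print.methylome_sample <- function(x, ...) {
  n4 <- sum(x$sites$mod_type == "4mC")
  n6 <- sum(x$sites$mod_type == "6mA")
  nm <- sum(x$sites$subtype == "M")
  no <- sum(x$sites$subtype == "O")
  cat(sprintf(
    "<methylome_sample> %s (%s): %d sites [4mC %d, 6mA %d%s]\n",
    x$sample_id, x$condition, nrow(x$sites), n4, n6,
    if (nm + no > 0) sprintf("; M %d, O %d", nm, no) else ""
  ))
  invisible(x)
}

#' Read per-base modification calls
#'
#' Reads methylation calls from either a PacBio basemods-style GFF3 (feature
#' types `m4C`/`m6A`, or `modified_base` with an attribute naming the
#' modification; QV in the score column or an `identificationQv` attribute;
#' read depth in a `coverage` attribute) or a plain TSV dialect with header
#' columns `sample_id`, `contig`, `position`, `strand`, `mod_type`, `qv`,
#' `coverage` (`.` for missing qv/coverage).
#'
#' The call filter is applied on read, even to pre-filtered files (idempotent):
#' a position counts as modified when its kinetic score QV is at least
#' `min_qv` and its coverage is strictly greater than
#' `min_coverage_exclusive`. Records with a missing QV or coverage fail a
#' positive threshold.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"basemods_gff3"`.
#' @param sample_id,condition Sample labels; for TSV input `sample_id`
#'   defaults to the file's `sample_id` column.
#' @param min_qv Minimum kinetic score (QV), inclusive. Default 100.
#' @param min_coverage_exclusive Coverage must exceed this. Default 25.
#' @param genome Optional `genome_seq` for reference-base validation.
#' @return A `methylome_sample`. The number of records dropped by the filter
#'   is attached as attribute `n_filtered` and reported via `message()`.
#' @export
read_methylome <- function(path, format = c("tsv", "basemods_gff3"),
                           sample_id = NULL, condition = NULL,
                           min_qv = 100L, min_coverage_exclusive = 25L,
                           genome = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, colClasses = "character", na.strings = ".",
                             check.names = FALSE)
    required <- c("sample_id", "contig", "position", "strand", "mod_type", "qv", "coverage")
    missing_cols <- setdiff(required, names(tab))
    if (length(missing_cols) > 0L) stop("TSV lacks columns: ", paste(missing_cols, collapse = ", "))
    if (is.null(sample_id)) {
      ids <- unique(tab$sample_id)
      sample_id <- if (length(ids) >= 1L) ids[1] else basename(path)
    }
    sites <- data.frame(
      contig = tab$contig,
      position = suppressWarnings(as.integer(tab$position)),
      strand = tab$strand,
      mod_type = tab$mod_type,
      qv = suppressWarnings(as.integer(tab$qv)),
      coverage = suppressWarnings(as.integer(tab$coverage)),
      stringsAsFactors = FALSE
    )
    if (anyNA(sites$position) || any(sites$position != suppressWarnings(as.numeric(tab$position)))) {
      stop("malformed coordinates in ", path)
    }
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    mod_type <- rep(NA_character_, length(gr))
    mod_type[type %in% c("m4C", "4mC")] <- "4mC"
    mod_type[type %in% c("m6A", "6mA")] <- "6mA"
    if (any(type == "modified_base")) {
      mcols_names <- names(S4Vectors::mcols(gr))
      attr_col <- intersect(c("modification", "mod_type", "base_mod"), mcols_names)
      if (length(attr_col) == 0L) stop("'modified_base' records lack a modification attribute")
      val <- as.character(S4Vectors::mcols(gr)[[attr_col[1]]])
      idx <- type == "modified_base"
      mod_type[idx & val %in% c("m4C", "4mC")] <- "4mC"
      mod_type[idx & val %in% c("m6A", "6mA")] <- "6mA"
    }
    if (anyNA(mod_type)) {
      stop("unknown mod type in GFF3: ", paste(unique(type[is.na(mod_type)]), collapse = ", "))
    }
    qv <- gr$score
    mcols_names <- names(S4Vectors::mcols(gr))
    if ("identificationQv" %in% mcols_names) {
      iq <- suppressWarnings(as.numeric(as.character(gr$identificationQv)))
      qv <- ifelse(is.na(qv), iq, qv)
    }
    coverage <- if ("coverage" %in% mcols_names) {
      suppressWarnings(as.integer(as.character(gr$coverage)))
    } else NA_integer_
    strand <- as.character(BiocGenerics::strand(gr))
    if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    sites <- data.frame(
      contig = as.character(GenomicRanges::seqnames(gr)),
      position = BiocGenerics::start(gr),
      strand = strand,
      mod_type = mod_type,
      qv = as.integer(round(qv)),
      coverage = coverage,
      stringsAsFactors = FALSE
    )
    if (is.null(sample_id)) sample_id <- sub("\\.gff3?$", "", basename(path))
  }

  n_in <- nrow(sites)
  pass_qv <- if (min_qv > 0) !is.na(sites$qv) & sites$qv >= min_qv else
    (is.na(sites$qv) | sites$qv >= min_qv)
  pass_cov <- if (min_coverage_exclusive >= 0) !is.na(sites$coverage) & sites$coverage > min_coverage_exclusive else
    (is.na(sites$coverage) | sites$coverage > min_coverage_exclusive)
  sites <- sites[pass_qv & pass_cov, , drop = FALSE]
  n_filtered <- n_in - nrow(sites)
  message(sprintf("read_methylome: %d records read, %d dropped by filter (QV >= %d, coverage > %d)",
                  n_in, n_filtered, min_qv, min_coverage_exclusive))

  if (is.null(condition)) condition <- sample_id
  out <- new_methylome_sample(sites, sample_id = sample_id, condition = condition,
                              genome = genome)
  attr(out, "n_filtered") <- n_filtered
  out
}

#' Write a methylome sample
#'
#' @param sample A `methylome_sample`.
#' @param path Output path.
#' @param format `"tsv"` (round-trip dialect) or `"basemods_gff3"`.
#' @return `path`, invisibly.
#' @export
write_methylome <- function(sample, path, format = c("tsv", "basemods_gff3")) {
  format <- match.arg(format)
  s <- sample$sites
  if (format == "tsv") {
    out <- data.frame(
      sample_id = sample$sample_id,
      contig = s$contig,
      position = s$position,
      strand = s$strand,
      mod_type = s$mod_type,
      qv = ifelse(is.na(s$qv), ".", as.character(s$qv)),
      coverage = ifelse(is.na(s$coverage), ".", as.character(s$coverage)),
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    type <- ifelse(s$mod_type == "4mC", "m4C", "m6A")
    lines <- sprintf(
      "%s\tkinModCall\t%s\t%d\t%d\t%s\t%s\t.\tcoverage=%s",
      s$contig, type, s$position, s$position,
      ifelse(is.na(s$qv), ".", as.character(s$qv)),
      s$strand,
      ifelse(is.na(s$coverage), ".", as.character(s$coverage))
    )
    writeLines(c("##gff-version 3", lines), path)
  }
  invisible(path)
}

#' Genome-wide methylation percentage
#'
#' Percentage of modifiable bases (both strands) carrying the modification:
#' `100 * n_sites(mod_type) / cytosines_both` for 4mC and
#' `/ adenines_both` for 6mA.
#'
#' @param sample A `methylome_sample`.
#' @param composition A `base_composition` from the genome the calls were
#'   made against.
#' @param mod_type `"4mC"` or `"6mA"`.
#' @return Percentage in `[0, 100]` (full precision; round only for display).
#' @export
methylation_percentage <- function(sample, composition, mod_type = c("4mC", "6mA")) {
  mod_type <- match.arg(mod_type)
  site_count_percentage(sum(sample$sites$mod_type == mod_type), composition, mod_type)
}

#' Methylation percentage from a bare site count
#'
#' Same computation as [methylation_percentage()] but starting from a site
#' count rather than a sample object — useful for consistency checks against
#' reported genome-wide counts.
#'
#' @param n_sites Number of modified sites (both strands).
#' @param composition A `base_composition`.
#' @param mod_type `"4mC"` or `"6mA"`.
#' @return Percentage in `[0, 100]`.
#' @export
site_count_percentage <- function(n_sites, composition, mod_type = c("4mC", "6mA")) {
  mod_type <- match.arg(mod_type)
  denom <- if (mod_type == "4mC") composition$cytosines_both else composition$adenines_both
  if (denom == 0L) stop("zero denominator: genome has no ", if (mod_type == "4mC") "cytosines" else "adenines")
  100 * n_sites / denom
}
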