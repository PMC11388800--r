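#' Methyltransferase recognition motif
#'
#' Describes the recognition sequence of a DNA methyltransferase and which
#' base within it is methylated. The default, 5'-GTACAG-3' with the second
#' adenine (0-based offset 4) as target, is the 6mA specificity found in
#' *Geobacter sulfurreducens*; both fields are configurable for other
#' enzymes.
#'
#' @param sequence Motif string over A/C/G/T (exact matching; no IUPAC
#'   degeneracy).
#' @param target_offset 0-based offset of the methylated base within the
#'   motif, counted along the motif's own 5'->3' direction. The base there
#'   must be A.
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(sequence = "GTACAG", target_offset = 4L) {
  stopifnot_scalar_string(sequence, "sequence")
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) stop("motif must be over A/C/G/T")
  target_offset <- as.integer(target_offset)
  if (target_offset < 0L || target_offset >= nchar(sequence)) {
    stop("target_offset outside motif")
  }
  if (substring(sequence, target_offset + 1L, target_offset + 1L) != "A") {
    stop("base at target_offset must be A (it is the methylated adenine)")
  }
  structure(list(sequence = sequence, target_offset = target_offset),
            class = "motif_spec")
}

#' Scan a genome for motif occurrences on both strands
#'
#' Finds every exact occurrence of the motif on either strand, including
#' overlapping ones. On circular genomes, occurrences spanning the origin are
#' also reported (coordinates wrap modulo the genome length).
#'
#' Coordinate convention: `start` is the forward coordinate of the motif's
#' 5'-most base *on its own strand*. For a minus-strand occurrence covering
#' forward interval `[s, s+m-1]`, the 5' end is at `s+m-1` and the target
#' base sits at `start - target_offset`; offsets are thus always counted in
#' the motif's own reading direction.
#'
#' @param genome A `genome_seq`.
#' @param motif A `motif_spec`.
#' @return Data frame with columns `contig`, `start`, `strand`,
#'   `target_position`, sorted by `target_position`.
#' @export
scan_motif <- function(genome, motif) {
  m <- nchar(motif$sequence)
  L <- genome$length
  if (m > L) stop("motif longer than genome")

  subject_seq <- genome$sequence
  if (genome$topology == "circular" && m > 1L) {
    subject_seq <- paste0(subject_seq, substring(subject_seq, 1L, m - 1L))
  }
  subject <- Biostrings::DNAString(subject_seq)

  wrap <- function(x) ((x - 1L) %% L) + 1L

  fwd <- Biostrings::matchPattern(motif$sequence, subject, fixed = TRUE)
  fwd_start <- BiocGenerics::start(fwd)
  fwd_start <- fwd_start[fwd_start <= L]

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif$sequence)))
  rev <- Biostrings::matchPattern(rc, subject, fixed = TRUE)
  rev_start <- BiocGenerics::start(rev)
  rev_start <- rev_start[rev_start <= L]

  occ <- data.frame(
    contig = rep(genome$contig_id, length(fwd_start) + length(rev_start)),
    start = c(wrap(fwd_start), wrap(rev_start + m - 1L)),
    strand = rep(c("+", "-"), c(length(fwd_start), length(rev_start))),
    target_position = c(
      wrap(fwd_start + motif$target_offset),
      wrap(rev_start + m - 1L - motif$target_offset)
    ),
    stringsAsFactors = FALSE
  )
  occ <- occ[order(occ$target_position, occ$strand), , drop = FALSE]
  rownames(occ) <- NULL

  # every reported target must read A on its own strand
  if (nrow(occ) > 0L) {
    base <- substring(genome$sequence, occ$target_position, occ$target_position)
    stopifnot(all(ifelse(occ$strand == "+", base == "A", base == "T")))
  }
  occ
}

#' Classify 6mA sites into M-6mA and O-6mA
#'
#' A 6mA site is motif-anchored (subtype `M`) when its (position, strand)
#' coincides with the target base of some motif occurrence on the same
#' strand; every other 6mA is `O`. 4mC sites are untouched. An empty
#' occurrence table classifies every 6mA as `O`.
#'
#' @param sample A `methylome_sample` called against the genome the
#'   occurrences were scanned from.
#' @param occurrences Occurrence table from [scan_motif()].
#' @return The sample with `subtype` filled in for all 6mA sites.
#' @export
classify_6ma <- function(sample, occurrences) {
  s <- sample$sites
  is6 <- s$mod_type == "6mA"
  targets <- character(0)
  if (!is.null(occurrences) && nrow(occurrences) > 0L) {
    targets <- paste(occurrences$contig, occurrences$target_position, occurrences$strand)
  }
  key <- paste(s$contig, s$position, s$strand)
  s$subtype[is6] <- ifelse(key[is6] %in% targets, "M", "O")
  s$subtype[!is6] <- "unset"
  sample$sites <- s
  sample
}

#' Fraction of 6mA that is motif-anchored (M-6mA)
#'
#' @param sample A classified `methylome_sample`.
#' @return `n_M / n_6mA` in `[0, 1]`; `NA` (with a warning) when the sample
#'   has no 6mA.
#' @export
m_fraction <- function(sample) {
  s <- sample$sites
  is6 <- s$mod_type == "6mA"
  if (any(s$subtype[is6] == "unset")) {
    stop("sample not classified; run classify_6ma() first")
  }
  n6 <- sum(is6)
  if (n6 == 0L) {
    warning("no 6mA sites; M-fraction undefined")
    return(NA_real_)
  }
  sum(s$subtype[is6] == "M") / n6
}

#' Export motif occurrences as BED6
#'
#' 0-based half-open intervals covering the full motif; the score column is
#' unused (`.`). Origin-spanning occurrences on circular genomes cannot be
#' represented as a single BED interval and are dropped with a warning.
#'
#' @param occurrences Table from [scan_motif()].
#' @param motif The `motif_spec` used for the scan.
#' @param path Output path.
#' @param genome_length Genome length (to detect origin-spanning intervals).
#' @return `path`, invisibly.
#' @export
write_occurrences_bed <- function(occurrences, motif, path, genome_length) {
  m <- nchar(motif$sequence)
  lo <- ifelse(occurrences$strand == "+", occurrences$start, occurrences$start - m + 1L)
  hi <- lo + m - 1L
  wrapped <- lo < 1L | hi > genome_length
  if (any(wrapped)) {
    warning(sum(wrapped), " origin-spanning occurrence(s) omitted from BED export")
  }
  keep <- occurrences[!wrapped, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\tmotif\t.\t%s",
                   keep$contig, lo[!wrapped] - 1L, hi[!wrapped], keep$strand)
  writeLines(lines, path)
  invisible(path)
}
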