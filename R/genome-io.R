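#' Read a single-contig genome from FASTA
#'
#' Reads a genome as a single chromosome. Bacterial chromosomes are usually
#' circular; topology is always stated explicitly by the caller, never guessed
#' from the file, because distance arithmetic across the replication origin
#' depends on it.
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `genome_seq`: a list with `contig_id`,
#'   `sequence` (uppercase character string over A/C/G/T/N), `topology`
#'   and `length`.
#' @details Multi-record FASTA files are an error rather than being silently
#'   concatenated: the analysis model is a single chromosome. Characters
#'   outside A/C/G/T/N (after upper-casing) are rejected.
#' @export
read_genome <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  if (length(set) > 1L) stop("multiple contigs unsupported (", length(set), " records in ", path, ")")
  sequence <- toupper(as.character(set[[1]]))
  contig_id <- sub("\\s.*$", "", names(set)[1])
  new_genome_seq(contig_id, sequence, topology)
}

#' Construct a genome object from an in-memory sequence
#'
#' @param contig_id Contig name.
#' @param sequence Character string over A/C/G/T/N (case-insensitive).
#' @param topology `"linear"` or `"circular"`.
#' @return A `genome_seq` object.
#' @export
new_genome_seq <- function(contig_id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot_scalar_string(sequence, "sequence")
  sequence <- toupper(sequence)
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) stop("non-ACGTN characters in sequence: ", paste(bad, collapse = ", "))
  structure(
    list(
      contig_id = contig_id,
      sequence = sequence,
      topology = topology,
      length = nchar(sequence)
    ),
    class = "genome_seq"
  )
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf(
    "<genome_seq> %s: %s bp, %s\n",
    x$contig_id, format(x$length, big.mark = ","), x$topology
  ))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome A `genome_seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome$sequence)
  names(dna) <- genome$contig_id
  Biostrings::writeXStringSet(dna, path, width = 80L)
  invisible(path)
}

#' Genome base composition with both-strand denominators
#'
#' Counts forward-strand A/C/G/T/N and derives the both-strand totals used as
#' denominators for genome-wide methylation percentages: every C on either
#' strand is a forward C or a forward G, and likewise for adenines.
#'
#' @param genome A `genome_seq`.
#' @return A `base_composition` object: forward counts `A`,`C`,`G`,`T`,`N`,
#'   plus `cytosines_both` (= C + G) and `adenines_both` (= A + T). N bases
#'   are excluded from both denominators.
#' @export
base_composition <- function(genome) {
  counts <- Biostrings::letterFrequency(
    Biostrings::DNAString(genome$sequence),
    letters = c("A", "C", "G", "T", "N")
  )
  counts <- as.integer(counts)
  names(counts) <- c("A", "C", "G", "T", "N")
  stopifnot(sum(counts) == genome$length)
  new_base_composition(counts)
}

#' Construct a base composition from forward-strand counts
#'
#' Used both by [base_composition()] and to carry a composition obtained
#' elsewhere (e.g. a published genome record) without the full sequence.
#'
#' @param counts Named integer vector with elements `A`,`C`,`G`,`T` and
#'   optionally `N`.
#' @return A `base_composition` object.
#' @export
new_base_composition <- function(counts) {
  for (b in c("A", "C", "G", "T")) {
    if (is.na(counts[b])) stop("missing count for base ", b)
  }
  n <- if ("N" %in% names(counts)) counts[["N"]] else 0L
  structure(
    list(
      A = as.integer(counts[["A"]]), C = as.integer(counts[["C"]]),
      G = as.integer(counts[["G"]]), T = as.integer(counts[["T"]]),
      N = as.integer(n),
      cytosines_both = as.integer(counts[["C"]] + counts[["G"]]),
      adenines_both = as.integer(counts[["A"]] + counts[["T"]])
    ),
    class = "base_composition"
  )
}

#' @export
print.base_composition <- function(x, ...) {
  cat(sprintf(
    "<base_composition> A=%d C=%d G=%d T=%d N=%d | cytosines(both)=%d adenines(both)=%d\n",
    x$A, x$C, x$G, x$T, x$N, x$cytosines_both, x$adenines_both
  ))
  invisible(x)
}
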