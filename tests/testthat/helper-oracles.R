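# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# naive O(L*m) sliding-window motif scan over both explicit strands,
# minus-strand hits mapped back to forward coordinates
naive_scan <- function(sequence, motif_seq, target_offset) {
  m <- nchar(motif_seq)
  L <- nchar(sequence)
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  rc <- revcomp(motif_seq)
  out <- list()
  for (s in seq_len(L - m + 1)) {
    win <- substring(sequence, s, s + m - 1)
    if (win == motif_seq) {
      out[[length(out) + 1]] <- data.frame(
        start = s, strand = "+", target_position = s + target_offset)
    }
    if (win == rc) {
      out[[length(out) + 1]] <- data.frame(
        start = s + m - 1, strand = "-",
        target_position = s + m - 1 - target_offset)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), strand = character(0),
                      target_position = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$target_position, res$strand), , drop = FALSE]
}

# O(n^2) all-pairs nearest distance
brute_nearest <- function(from, to) {
  vapply(from, function(p) min(abs(p - to)), numeric(1))
}

# per-base recount of feature methylation
brute_feature_level <- function(sites_pos, genome_seq, start, end, letters) {
  cnt <- sum(sites_pos >= start & sites_pos <= end)
  seg <- strsplit(substring(genome_seq, start, end), "")[[1]]
  bases <- sum(seg %in% letters)
  list(site_count = cnt, modifiable_bases = bases,
       level = if (bases == 0) NA_real_ else cnt / bases)
}

# random DNA string
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# minimal site table builder
site_df <- function(position, strand, mod_type, qv = 150L, coverage = 50L,
                    contig = "chr") {
  data.frame(contig = contig, position = position, strand = strand,
             mod_type = mod_type, qv = qv, coverage = coverage,
             stringsAsFactors = FALSE)
}
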