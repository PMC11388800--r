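#' Read a gene annotation
#'
#' Accepts GFF3 (feature types `gene` or `CDS`; the identifier is taken from
#' `ID`, `locus_tag` or `gene_id`, in that order) or a TSV with header columns
#' `gene_id`, `contig`, `start`, `end`, `strand`. Coordinates are 1-based
#' inclusive. Overlapping genes are permitted and retained.
#'
#' @param path Input file.
#' @param format `"gff3"` or `"tsv"`.
#' @param genome Optional `genome_seq`; when supplied, features outside the
#'   genome are an error.
#' @return Data frame of features sorted by `start`, columns `gene_id`,
#'   `contig`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path, format = c("tsv", "gff3"), genome = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    required <- c("gene_id", "contig", "start", "end", "strand")
    missing_cols <- setdiff(required, names(tab))
    if (length(missing_cols) > 0L) stop("annotation TSV lacks columns: ", paste(missing_cols, collapse = ", "))
    features <- data.frame(
      gene_id = as.character(tab$gene_id),
      contig = as.character(tab$contig),
      start = as.integer(tab$start),
      end = as.integer(tab$end),
      strand = as.character(tab$strand),
      stringsAsFactors = FALSE
    )
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
    if (length(gr) == 0L) stop("no gene/CDS features in ", path)
    mcols_names <- names(S4Vectors::mcols(gr))
    id_col <- intersect(c("ID", "locus_tag", "gene_id"), mcols_names)
    if (length(id_col) == 0L) stop("GFF3 features carry no ID/locus_tag/gene_id attribute")
    features <- data.frame(
      gene_id = as.character(S4Vectors::mcols(gr)[[id_col[1]]]),
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr),
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      stringsAsFactors = FALSE
    )
  }
  if (any(features$start > features$end)) stop("feature with start > end")
  if (!all(features$strand %in% c("+", "-"))) stop("feature strand must be '+' or '-'")
  if (!is.null(genome)) {
    if (any(features$start < 1L) || any(features$end > genome$length)) {
      stop("feature coordinates outside genome")
    }
  }
  features <- features[order(features$start, features$end, features$gene_id), , drop = FALSE]
  rownames(features) <- NULL
  features
}

#' Write a gene annotation to TSV
#'
#' @param features Annotation data frame (as from [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(features, path) {
  utils::write.table(features[, c("gene_id", "contig", "start", "end", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with columns `gene_id`, `log2fc`, `padj`. A gene is called
#' differentially expressed when its adjusted p-value is strictly below
#' `alpha`; direction follows the sign of the log2 fold change.
#'
#' @param path Input file.
#' @param alpha Significance threshold on the adjusted p-value (strict `<`).
#' @return Data frame with `gene_id`, `log2fc`, `padj`, `direction`
#'   (`up`/`down`/`ns`).
#' @export
read_deg_table <- function(path, alpha = 0.05) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene_id", "log2fc", "padj")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) stop("DEG table lacks columns: ", paste(missing_cols, collapse = ", "))
  tab$log2fc <- as.numeric(tab$log2fc)
  tab$padj <- as.numeric(tab$padj)
  if (anyNA(tab$padj) || any(tab$padj < 0) || any(tab$padj > 1)) {
    stop("padj outside [0, 1]")
  }
  deg_table(tab[, required], alpha = alpha)
}

#' Assign DEG direction calls to a fold-change table
#'
#' @param tab Data frame with `gene_id`, `log2fc`, `padj`.
#' @param alpha Adjusted-p threshold (strict `<`).
#' @return The table with a `direction` column added.
#' @export
deg_table <- function(tab, alpha = 0.05) {
  sig <- tab$padj < alpha
  tab$direction <- ifelse(sig & tab$log2fc > 0, "up",
                   ifelse(sig & tab$log2fc < 0, "down", "ns"))
  tab
}

#' Write a DEG table to TSV
#'
#' @param tab DEG data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(tab, path) {
  utils::write.table(tab[, c("gene_id", "log2fc", "padj")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
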