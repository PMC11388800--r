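#' Assemble a pipeline run configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()]. All
#' paths are checked at construction. The parameter block is echoed into
#' the run summary so a report is self-describing.
#'
#' @param genome_path FASTA genome (single contig).
#' @param topology Genome topology.
#' @param methylome_paths Named character vector: condition label -> TSV
#'   methylome path (the first element is taken as the reference/control
#'   condition).
#' @param annotation_path Optional annotation (TSV), or `NULL`.
#' @param deg_paths Optional named vector of DEG TSVs; names are contrast
#'   labels of the form `<control>_vs_<exposed>` where `<exposed>` is a
#'   condition label.
#' @param out_dir Output directory for the report bundle.
#' @param min_qv,min_coverage_exclusive Modification-call filter.
#' @param motif A [motif_spec()].
#' @param max_distance,n_bins Histogram specification.
#' @param thresholds Cumulative-curve thresholds (bp).
#' @param upstream_length Upstream window (bp).
#' @param alpha DEG significance threshold.
#' @return A `run_config` list.
#' @export
run_config <- function(genome_path, topology = "circular", methylome_paths,
                       annotation_path = NULL, deg_paths = NULL,
                       out_dir, min_qv = 100L, min_coverage_exclusive = 25L,
                       motif = motif_spec(), max_distance = 250L, n_bins = 25L,
                       thresholds = c(1L, 2L, 5L, 10L, 25L, 50L, 100L, 250L),
                       upstream_length = 200L, alpha = 0.05) {
  paths <- c(genome_path, methylome_paths, annotation_path, deg_paths)
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths) > 0L) {
    stop("missing input file(s): ", paste(missing_paths, collapse = ", "))
  }
  if (is.null(names(methylome_paths)) || any(names(methylome_paths) == "")) {
    stop("methylome_paths must be named by condition label")
  }
  structure(
    list(genome_path = genome_path, topology = topology,
         methylome_paths = methylome_paths,
         annotation_path = annotation_path, deg_paths = deg_paths,
         out_dir = out_dir, min_qv = as.integer(min_qv),
         min_coverage_exclusive = as.integer(min_coverage_exclusive),
         motif = motif, max_distance = as.integer(max_distance),
         n_bins = as.integer(n_bins), thresholds = as.integer(thresholds),
         upstream_length = as.integer(upstream_length), alpha = alpha),
    class = "run_config"
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full crosstalk analysis
#'
#' Reads and filters every input, classifies 6mA against the motif scan,
#' computes per-sample summaries, adjacent-distance histograms and power-law
#' fits (per class and strand mode), nearest-4mC cumulative curves for O-
#' and M-6mA, cross-sample site overlaps, pairwise O-to-M distance multiset
#' overlaps, and — when annotation and DEG tables are present — gene-level
#' methylation, DEG-versus-genome summaries, upstream-window summaries and
#' level correlations. Without DEG inputs the gene-association block is
#' skipped with a notice, not an error. All results are written as TSV plus
#' a JSON run summary; reruns on identical inputs are byte-identical (the
#' pipeline draws no random numbers).
#'
#' @param config A [run_config()].
#' @return The report bundle as a (invisible) list mirroring the files
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_genome(config$genome_path, topology = config$topology)
  composition <- base_composition(genome)
  occ <- scan_motif(genome, config$motif)

  labels <- names(config$methylome_paths)
  samples <- lapply(labels, function(lbl) {
    sm <- read_methylome(config$methylome_paths[[lbl]], format = "tsv",
                         sample_id = lbl, condition = lbl,
                         min_qv = config$min_qv,
                         min_coverage_exclusive = config$min_coverage_exclusive,
                         genome = genome)
    if (!all(sm$sites$contig == genome$contig_id)) {
      stop("methylome ", lbl, " refers to a contig other than ", genome$contig_id)
    }
    classify_6ma(sm, occ)
  })
  names(samples) <- labels

  # ---- per-sample summary ------------------------------------------------
  summary_df <- do.call(rbind, lapply(labels, function(lbl) {
    sm <- samples[[lbl]]
    s <- sm$sites
    data.frame(
      sample = lbl, condition = sm$condition,
      n_4mC = sum(s$mod_type == "4mC"),
      n_6mA = sum(s$mod_type == "6mA"),
      n_M6mA = sum(s$subtype == "M"),
      n_O6mA = sum(s$subtype == "O"),
      pct_4mC = methylation_percentage(sm, composition, "4mC"),
      pct_6mA = methylation_percentage(sm, composition, "6mA"),
      m_fraction = if (sum(s$mod_type == "6mA") > 0) m_fraction(sm) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  write_tsv(summary_df, file.path(config$out_dir, "sample_summary.tsv"))

  # ---- adjacent-distance histograms and power-law fits --------------------
  fits <- list()
  hist_rows <- list()
  for (lbl in labels) {
    for (cls in c("4mC", "6mA")) {
      for (mode in c("double", "positive", "negative")) {
        pos <- class_positions(samples[[lbl]], cls, strand_mode = mode)
        ds <- adjacent_distances(pos, topology = genome$topology,
                                 genome_length = genome$length,
                                 from_class = cls, strand_mode = mode)
        h <- bin_histogram(ds, config$max_distance, config$n_bins)
        hist_rows[[paste(lbl, cls, mode)]] <- data.frame(
          sample = lbl, class = cls, strand_mode = mode,
          bin_lo = h$bin_edges[-length(h$bin_edges)],
          bin_hi = h$bin_edges[-1], mid = h$mid, count = h$counts,
          stringsAsFactors = FALSE
        )
        fit_ok <- sum(h$counts > 0) >= 3L
        f <- if (fit_ok) fit_power_law(h) else NULL
        fits[[paste(lbl, cls, mode)]] <- data.frame(
          sample = lbl, class = cls, strand_mode = mode,
          a = if (fit_ok) f$a else NA_real_,
          b = if (fit_ok) f$b else NA_real_,
          r_squared = if (fit_ok) f$r_squared else NA_real_,
          n_bins_fit = if (fit_ok) f$n_bins_fit else 0L,
          n_distances = length(ds$distances),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  write_tsv(do.call(rbind, hist_rows), file.path(config$out_dir, "adjacent_histograms.tsv"))
  fits_df <- do.call(rbind, fits)
  rownames(fits_df) <- NULL
  write_tsv(fits_df, file.path(config$out_dir, "power_law_fits.tsv"))

  # ---- nearest-4mC cumulative curves for O-6mA and M-6mA ------------------
  curve_rows <- list()
  for (lbl in labels) {
    ds_o <- to_4mc_distances(samples[[lbl]], "O6mA")
    ds_m <- to_4mc_distances(samples[[lbl]], "M6mA")
    co <- cumulative_curve(ds_o, config$thresholds, strict = TRUE)
    cm <- cumulative_curve(ds_m, config$thresholds, strict = TRUE)
    curve_rows[[lbl]] <- data.frame(
      sample = lbl, threshold = config$thresholds,
      frac_O6mA_lt = co$cumulative_fraction,
      frac_M6mA_lt = cm$cumulative_fraction,
      n_O6mA = co$n, n_M6mA = cm$n,
      stringsAsFactors = FALSE
    )
  }
  curves_df <- do.call(rbind, curve_rows)
  rownames(curves_df) <- NULL
  write_tsv(curves_df, file.path(config$out_dir, "nearest_4mc_cumulative.tsv"))

  # ---- cross-sample overlaps ----------------------------------------------
  overlaps <- list()
  if (length(samples) >= 2L) {
    for (cls in c("4mC", "6mA", "O6mA")) {
      ov <- site_overlap(samples, cls)
      overlaps[[cls]] <- ov
      write_tsv(
        data.frame(sample = ov$sample_ids, count = ov$counts,
                   fraction_shared = ov$fraction_shared_per_sample,
                   stringsAsFactors = FALSE),
        file.path(config$out_dir, paste0("site_overlap_", cls, ".tsv"))
      )
      jm <- as.data.frame(ov$jaccard)
      jm <- cbind(sample = rownames(ov$jaccard), jm)
      write_tsv(jm, file.path(config$out_dir, paste0("jaccard_", cls, ".tsv")))
    }
    # pairwise O-to-M distance multiset overlaps
    om <- lapply(samples, o_to_m_distances)
    pair_rows <- list()
    for (i in seq_along(labels)) {
      for (j in seq_along(labels)) {
        if (i >= j) next
        mo <- distance_multiset_overlap(om[[i]], om[[j]])
        pair_rows[[paste(i, j)]] <- data.frame(
          sample_a = labels[i], sample_b = labels[j],
          size_a = mo$size_a, size_b = mo$size_b,
          intersection_size = mo$intersection_size,
          fraction_of_a = mo$fraction_of_a, fraction_of_b = mo$fraction_of_b,
          stringsAsFactors = FALSE
        )
      }
    }
    write_tsv(do.call(rbind, pair_rows),
              file.path(config$out_dir, "o_to_m_multiset_overlap.tsv"))
  }

  # ---- gene association ---------------------------------------------------
  gene_block <- NULL
  if (!is.null(config$annotation_path) && !is.null(config$deg_paths)) {
    features <- read_annotation(config$annotation_path, format = "tsv",
                                genome = genome)
    deg_tables <- lapply(config$deg_paths, read_deg_table, alpha = config$alpha)
    names(deg_tables) <- names(config$deg_paths)
    control <- labels[1]

    body_levels <- lapply(samples, feature_methylation, features = features,
                          genome = genome, region = "body", mod_class = "4mC")
    up_levels_4mc <- lapply(samples, feature_methylation, features = features,
                            genome = genome, region = "upstream200",
                            mod_class = "4mC",
                            upstream_length = config$upstream_length)
    up_levels_o <- lapply(samples, feature_methylation, features = features,
                          genome = genome, region = "upstream200",
                          mod_class = "O6mA",
                          upstream_length = config$upstream_length)
    for (lbl in labels) {
      write_tsv(body_levels[[lbl]],
                file.path(config$out_dir, paste0("gene_levels_4mC_", lbl, ".tsv")))
    }

    deg_rows <- list()
    cor_rows <- list()
    up_rows <- list()
    for (contrast in names(deg_tables)) {
      exposed <- sub("^.*_vs_", "", contrast)
      if (!exposed %in% labels) {
        message("contrast ", contrast, " has no matching methylome; skipped")
        next
      }
      dt <- deg_tables[[contrast]]
      g_lvl <- genome_level(samples[[exposed]], composition, "4mC")
      summ <- categorize_degs(dt, body_levels[[exposed]], g_lvl)
      summ <- cbind(contrast = contrast, genome_level = g_lvl, summ)
      deg_rows[[contrast]] <- summ

      for (dir in c("down", "up")) {
        ids <- dt$gene_id[dt$direction == dir]
        x <- body_levels[[control]]$level[match(ids, body_levels[[control]]$gene_id)]
        y <- body_levels[[exposed]]$level[match(ids, body_levels[[exposed]]$gene_id)]
        ok <- !is.na(x) & !is.na(y)
        res <- if (sum(ok) >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
          pearson_correlation(x[ok], y[ok])
        } else list(r = NA_real_, p = NA_real_, n = sum(ok))
        cor_rows[[paste(contrast, dir)]] <- data.frame(
          contrast = contrast, direction = dir,
          r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE
        )
      }

      for (mc in c("4mC", "O6mA")) {
        lv <- if (mc == "4mC") up_levels_4mc else up_levels_o
        for (dir in c("down", "up")) {
          ids <- dt$gene_id[dt$direction == dir]
          ctrl <- lv[[control]]$level[match(ids, lv[[control]]$gene_id)]
          expd <- lv[[exposed]]$level[match(ids, lv[[exposed]]$gene_id)]
          ok <- !is.na(ctrl) & !is.na(expd)
          up_rows[[paste(contrast, mc, dir)]] <- data.frame(
            contrast = contrast, mod_class = mc, direction = dir,
            n = sum(ok),
            n_higher_than_control = sum(expd[ok] > ctrl[ok]),
            n_lower_than_control = sum(expd[ok] < ctrl[ok]),
            fraction_zero = if (sum(ok) == 0L) NA_real_ else mean(expd[ok] == 0),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    deg_df <- do.call(rbind, deg_rows); rownames(deg_df) <- NULL
    cor_df <- do.call(rbind, cor_rows); rownames(cor_df) <- NULL
    up_df <- do.call(rbind, up_rows); rownames(up_df) <- NULL
    write_tsv(deg_df, file.path(config$out_dir, "deg_4mc_summary.tsv"))
    write_tsv(cor_df, file.path(config$out_dir, "deg_level_correlations.tsv"))
    write_tsv(up_df, file.path(config$out_dir, "deg_upstream_summary.tsv"))

    # O-6mA-modified gene sets: overlap across samples, and against DEGs
    o_genes <- lapply(samples, function(sm) {
      fl <- feature_methylation(sm, features, genome, "body", "O6mA")
      fl$gene_id[fl$site_count > 0L]
    })
    if (length(o_genes) >= 2L) {
      venn <- gene_set_overlap(o_genes[seq_len(min(4L, length(o_genes)))])
      write_tsv(venn, file.path(config$out_dir, "o6ma_gene_overlap.tsv"))
    }
    deg_venn_rows <- list()
    for (contrast in names(deg_tables)) {
      exposed <- sub("^.*_vs_", "", contrast)
      if (!exposed %in% labels) next
      dt <- deg_tables[[contrast]]
      degs <- dt$gene_id[dt$direction != "ns"]
      v <- gene_set_overlap(list(DEG = degs, O6mA = o_genes[[exposed]]))
      v <- cbind(contrast = contrast, v)
      deg_venn_rows[[contrast]] <- v
    }
    if (length(deg_venn_rows) > 0L) {
      dv <- do.call(rbind, deg_venn_rows); rownames(dv) <- NULL
      write_tsv(dv, file.path(config$out_dir, "deg_o6ma_gene_overlap.tsv"))
    }
    gene_block <- list(deg_summary = deg_df, correlations = cor_df,
                       upstream_summary = up_df)
  } else {
    message("annotation or DEG tables absent; gene-association block skipped")
  }

  # ---- JSON run summary ---------------------------------------------------
  input_paths <- c(genome = config$genome_path, config$methylome_paths,
                   annotation = config$annotation_path, config$deg_paths)
  summary_json <- list(
    package = "methcrosstalk",
    version = as.character(utils::packageVersion("methcrosstalk")),
    parameters = list(
      min_qv = config$min_qv,
      min_coverage_exclusive = config$min_coverage_exclusive,
      motif = config$motif$sequence,
      target_offset = config$motif$target_offset,
      max_distance = config$max_distance, n_bins = config$n_bins,
      thresholds = config$thresholds,
      upstream_length = config$upstream_length, alpha = config$alpha,
      topology = config$topology
    ),
    input_md5 = as.list(tools::md5sum(input_paths)),
    samples = summary_df,
    power_law_fits = fits_df,
    correlations = if (!is.null(gene_block)) gene_block$correlations else NULL
  )
  jsonlite::write_json(summary_json, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")

  invisible(list(
    summary = summary_df, fits = fits_df, curves = curves_df,
    overlaps = overlaps, gene_block = gene_block
  ))
}
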