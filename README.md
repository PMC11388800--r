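# methcrosstalk

Analysis of bacterial 4mC/6mA methylome crosstalk in R.

Prokaryotic genomes carry two prevalent DNA modifications: N4-methylcytosine
(4mC) and N6-methyladenine (6mA), called at base resolution from
single-molecule sequencing. In *Geobacter sulfurreducens*, one
methyltransferase specificity (5′-GTACAG-3′, second adenine methylated)
pins a subset of 6mA to fixed genomic positions ("M-6mA"), while the
remaining "O-6mA" and the ~20-fold more numerous 4mC vary between samples.
`methcrosstalk` is for researchers asking whether these site classes are
spatially coupled — a methylation *cascade* in which each class references
the previous one — and whether any of it relates to gene expression.

The package implements, as composable and individually tested operations:

* **IO**: single-contig genome FASTA; methylation calls in a PacBio
  basemods-style GFF3 dialect or a plain TSV, filtered at the standard
  call thresholds (kinetic score QV ≥ 100, coverage > 25×); annotation
  (GFF3/TSV) and differential-expression tables.
* **Motif classification**: both-strand exact motif scanning (overlapping
  and origin-spanning matches included) and partition of 6mA into
  M-6mA/O-6mA.
* **Distance statistics**: adjacent and nearest-neighbour distances per
  strand mode, the 25-bin (0,250] frequency histogram, the allometric fit
  *y = a·x^b* (Levenberg–Marquardt, log–log-OLS start), and cumulative
  distance curves.
* **Overlap**: cross-sample site overlap (per-sample and Jaccard
  conventions), multiset overlap of distance spectra, Venn region counts
  for 2–4 gene sets.
* **Gene association**: per-gene and upstream-200 bp methylation levels
  (sites per modifiable base, both strands), DEG-versus-genome level
  summaries, Pearson correlations.
* **Synthetic data**: a seeded generator of cascade-structured methylomes
  (M-6mA anchors O-6mA; O-6mA seeds 4mC within a few bp; 4mC spacing
  follows a power law with exponent −1.2), multi-condition families with
  partial site retention, and matched annotations/DEG tables.
* **Pipeline**: `run_pipeline()` composes everything into a deterministic
  TSV + JSON report bundle.

## Worked example

```r
library(methcrosstalk)

# a synthetic study: 1 Mb genome, 400 GTACAG copies, four conditions
cfg    <- synthetic_config(seed = 1)
genome <- generate_genome(cfg)
occ    <- scan_motif(genome, cfg$motif)
fam    <- generate_sample_family(genome, cfg)
fam    <- lapply(fam, classify_6ma, occurrences = occ)

fam$control
#> <methylome_sample> control (control): 22365 sites [4mC 21300, 6mA 1065; M 400, O 665]

m_fraction(fam$control)
#> [1] 0.3755869

# power-law spacing of 4mC
pos <- sort(unique(fam$control$sites$position[fam$control$sites$mod_type == "4mC"]))
fit <- fit_power_law(bin_histogram(adjacent_distances(pos, "circular", genome$length)))
fit
#> <power_law_fit> y = 5.789e+04 * x^-1.114, R^2 = 0.9988 (25 bins)

# crosstalk: O-6mA sit much closer to 4mC than M-6mA do
cumulative_curve(to_4mc_distances(fam$control, "O6mA"), 5)$cumulative_fraction
#> [1] 0.7819549
cumulative_curve(to_4mc_distances(fam$control, "M6mA"), 5)$cumulative_fraction
#> [1] 0.225

# cross-sample site overlap
site_overlap(fam, "4mC")
#> <overlap_result> 4mC over 4 samples: |intersection|=6771, |union|=40992
#>   shared fraction per sample: control=0.318, 1G=0.318, 10G=0.318, 100G=0.318
```

Reading those numbers: ~38% of 6mA is motif-anchored; adjacent-4mC
distance frequencies decay as a power law with exponent ≈ −1.1 (the
generator's configured −1.2, recovered through binning and fitting); 78%
of O-6mA lie within 5 bp of a 4mC against 23% for M-6mA — the spatial
signature of O-6mA-referenced 4mC seeding; and under 65% per-condition
site retention, about 32% of any sample's 4mC positions are shared by all
four conditions.

The same analysis runs on real inputs via `run_pipeline()`:

```r
cfg <- run_config(
  genome_path     = "genome.fasta",
  methylome_paths = c(control = "control.tsv", `1G` = "1G.tsv"),
  annotation_path = "annotation.tsv",
  deg_paths       = c(control_vs_1G = "deg_1G.tsv"),
  out_dir         = "report"
)
run_pipeline(cfg)
```

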