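Package: methcrosstalk
Title: Crosstalk Analysis of 4mC and 6mA Bacterial Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of prokaryotic N4-methylcytosine (4mC) and
    N6-methyladenine (6mA) methylomes called from single-molecule
    sequencing. Classifies 6mA sites into motif-anchored M-6mA versus
    other O-6mA, computes inter-site distance distributions with
    allometric (power-law) fits, cross-sample overlap statistics,
    and gene/upstream methylation-expression associations. Includes a
    seeded generator of cascade-structured synthetic methylomes
    (M-6mA anchors O-6mA, O-6mA seeds 4mC, 4mC propagates with a
    power-law distance kernel) so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    GenomicRanges,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
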