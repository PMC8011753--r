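Package: pacseq
Title: Direct Guide-RNA Detection and Power Analysis for Single-Cell CRISPR Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational pipeline for single-cell CRISPR screens in which
    polyadenylated guide RNAs are captured directly in droplet scRNA-seq.
    Maps gRNA-enriched reads to a known guide panel with a local aligner,
    collapses them to UMI-unique cell-by-guide counts, fits a per-guide
    two-component binomial mixture by expectation-maximization to call guide
    presence against background noise, assigns cells carrying exactly one
    guide, and computes detection rates. Includes barcode-rank (knee) and
    median-absolute-deviation quality control, log-normalization, Wilcoxon
    rank-sum differential expression with Bonferroni correction, and a
    simulation-based power framework that injects monoallelic (halved) and
    biallelic (zeroed) loss of expression into genes bucketed by baseline
    expression to predict the number of treatment cells required for
    detection, with and without independent filtering. A synthetic-data
    generator produces droplet-like UMI matrices, guide count matrices with
    ground truth, and paired gRNA-library FASTQ files for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Biostrings,
    mclust,
    stats,
    methods,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
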