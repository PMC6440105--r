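Package: bsqc
Title: Quality Control and Aggregation for Bisulfite Sequencing Methylation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-sample quality control and cohort-level aggregation for
    bisulfite sequencing DNA methylation data (WGBS, RRBS, hybrid-selection
    and single-cell protocols). Reads Bismark-dialect per-CpG coverage files
    and methylation-call-tagged alignments, computes a standard panel of QC
    metrics (read counts, CpG coverage at thresholds, M-bias profiles,
    downsampling saturation curves, methylation discretization, genomic
    feature coverage, bisulfite conversion rate, CpG density and methylation
    value distributions), optionally estimated from a random subsample of
    sites for scalability, and combines per-sample data into coverage and
    methylation count matrices annotated with sample metadata. Includes a
    synthetic bisulfite data simulator with known ground truth, plain-text
    and self-contained HTML QC reports, and a command-line interface for the
    two-stage per-sample / aggregation workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    withr,
    Rsamtools,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
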