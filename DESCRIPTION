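Package: bsmethkit
Title: Analysis of Base-Resolution Bisulfite Sequencing Methylation Profiles
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for base-resolution DNA methylation analysis from
    bisulfite sequencing experiments (RRBS, WGBS and related protocols).
    Reads per-cytosine methylation call tables and Bismark-style SAM
    alignments; applies coverage and base-quality filters; summarizes
    calls over tiling windows or user-supplied regions; characterizes
    samples with descriptive statistics, correlation, hierarchical
    clustering and principal component analysis on commonly covered
    cytosines; detects differentially methylated cytosines and regions
    with binomial logistic regression (with optional covariates) or
    Fisher's exact test, with sliding-linear-model or Benjamini-Hochberg
    q-values; annotates calls against transcription start sites, gene
    parts, CpG islands and shores, and custom regions; adjusts apparent
    5mC levels for matched 5hmC measurements; and exports bedGraph
    tracks.  A synthetic-data module simulates methylomes, alignments
    and feature sets with known ground truth for testing and
    calibration.  A command-line interface exposes the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
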