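Package: barfit
Title: Bar-Seq Fitness Profiling of Barcoded Deletion Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pooled competitive fitness profiling of molecularly
    barcoded deletion strain collections (Bar-Seq). Counts UPTAG/DOWNTAG
    barcodes from multiplexed FASTQ reads under a full-length at-most-one-
    mismatch identification rule, tests per-strain abundance changes between
    growth stages with a negative-binomial model (median-of-ratios size
    factors, moment dispersion with a fitted trend, Wald test on the log2
    ratio of group means), classifies haplo-proficient and haplo-insufficient
    strains, clusters co-fitness profiles by partitioning around medoids with
    exact binomial class-enrichment tests, and screens arrayed colony sizes
    with plate normalization plus a two-component normal mixture. Includes a
    ground-truthed simulator of competitive pool growth, barcode reads,
    colony plates and growth curves for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    cluster
Config/testthat/edition: 3
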