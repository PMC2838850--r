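Package: cgcqtl
Title: Keyword-Based Candidate Gene Scoring and QTL Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores genes for disease relevance by weighted keyword matching
    against per-gene descriptive text records (the Candidate Gene Capture,
    CGC, score), partitions scored genes into quantitative trait locus (QTL)
    versus non-QTL genomic regions and tests each score stratum for
    enrichment, and detects QTL pairs from two experimental crosses that
    share an unexpectedly high number of cross-referenced gene pairs using
    Yates-corrected chi-square tests. Includes a seeded synthetic-data
    generator emulating gene catalogs, QTL interval tables, keyword-bearing
    record corpora and hyperlink graphs, plus a command-line interface for
    end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    optparse,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
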