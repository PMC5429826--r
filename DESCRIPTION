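Package: exomecov
Title: Cohort Coverage Quality Assessment for Exome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality assessment of read-depth coverage in exome-sequencing
    cohorts. Implements the Cohort Coverage Sparseness (CCS) score, the
    per-region cohort median of the fraction of bases covered by fewer than a
    cutoff number of reads, and the Unevenness (U_E) score, a peak-geometry
    statistic computed on the LOWESS-smoothed cohort median depth profile with
    hill-climbing extremum detection. Includes consensus exon annotation
    merging and capture-target intersection, per-base depth file parsing
    (BEDTools coverage -d and genomecov -d dialects), sample-level QC, GC
    content and repeat-element trough concordance, cohort-level statistical
    summaries, and a synthetic cohort depth simulator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
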