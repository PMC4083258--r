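Package: capqc
Title: Quality Control Metrics for Targeted Sequence Capture Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation of targeted (exome) capture sequencing experiments:
    builds capture target designs from annotation interval tracks (merging
    and short-region padding in BED coordinates), computes per-target-base
    depth of coverage and region completeness from aligned reads, summarises
    per-sample performance (read accounting, mean depth, region and base
    completeness at depth thresholds, on-target specificity), measures
    multi-sample reproducibility (consistently, never and variably covered
    bases and regions), simulates the effect of pre-capture pooling by seeded
    fractional read subsampling, and computes qPCR amplification efficiency
    and capture fold enrichment from standard curves and threshold cycles.
    Includes a deterministic synthetic-data generator (toy genome, target
    design, aligned paired reads with configurable on-target fraction,
    duplicate rate and region dropout) so every stage can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
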