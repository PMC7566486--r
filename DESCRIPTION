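Package: cocna
Title: Genomically Co-Localized Co-Expression Signatures and Driver Copy-Number Calls
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers pan-cancer co-expression signatures formed by genomically
    adjacent genes (attractor metagenes restricted to sliding genomic windows) from
    multi-cohort tumor expression data, and designates them as driver amplifications
    or deletions by combining a permutation test on the association between signature
    expression and copy-number levels with recurrence of the alteration across cancer
    types. Includes gene-level mapping of copy-number segments, a spline-based mutual
    information association measure with weighted-median pan-cancer aggregation,
    normal-sample-derived amplification/deletion thresholds, and a synthetic
    multi-cohort generator with planted events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    splines,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
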