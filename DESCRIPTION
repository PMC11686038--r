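Package: cadsr
Title: Chromatin Accessibility Dynamics Classification for Reprogramming
    Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies chromatin accessibility dynamics (CADs) over
    ATAC-seq time courses of somatic-cell reprogramming: builds an
    integrated peak background, assigns per-region open/close trajectory
    classes (PO, CO1-CO5, OC1-OC5), compares peak sets across
    reprogramming systems and derives factor-synergy patterns, integrates
    CUT&Tag factor-binding peaks to separate direct from indirect effects
    and predicted from actual co-binding, and classifies genes into
    cross-system differential-expression clusters with endpoint
    fold-change bins. Ships a synthetic-data generator that plants ground
    truth for every classifier, and a config-driven pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    limma,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
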