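Package: cnvscan
Title: Segment-Based Case-Control Association Testing for Copy Number
    Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A genome-wide copy-number-variant (CNV) case/control
    association pipeline for SNP-array call sets. Applies per-sample
    quality control (call rate, Log R Ratio noise, GC wave factor, call
    count, duplicate and principal-component outlier exclusion), counts
    deletion and duplication carriers at every array probe, tests
    case/control frequency differences with two-sided Fisher exact
    tests, collapses runs of significant probes into CNV regions with
    local p-value minima, screens regions against positional, peninsula,
    GC-content, coverage and sample-bias artifact filters, replicates
    findings with principal-component-corrected logistic regression and
    Fisher's-method p-value combination, and annotates regions with
    overlapped or nearest genes plus hypergeometric category enrichment.
    Includes a synthetic-data generator that plants recurrent CNV
    regions, common-CNV peninsula substrates, recurrently contributing
    bias samples and poor-quality samples into case/control cohorts for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
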