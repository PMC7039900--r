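Package: spliceprofiler
Title: Splicing Profiles and Aberrant Splicing Calls from Targeted RNA-Seq Junction Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies and quantifies non-canonical splicing events from
    splice-junction count tables produced by targeted (capture) RNA
    sequencing of a gene panel. Events are defined relative to one reference
    isoform per gene, quantified as percent spliced in (PSI), aggregated
    across a healthy-control cohort into a reference splicing profile, and
    compared per patient sample with a one-sample t test under Holm-Sidak
    multiple-testing correction to call statistically aberrant splicing.
    Includes a seed-reproducible synthetic cohort generator with known event
    truth for end-to-end validation, sample-level coverage QC, and
    diagnostic-yield arithmetic for cohort reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rtracklayer,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
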