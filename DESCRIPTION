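Package: mirepress
Title: Abundance-Weighted miRNA Target Repression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analyses miRNA expression profiles by apportioning each miRNA's
    transcripts-per-million abundance across its predicted mRNA targets in
    proportion to interaction repression scores, accumulating a per-mRNA
    comprehensive repression mass, and testing each mRNA's (or each
    miRNA-mRNA interaction's) share of total repression between tumour
    samples and an averaged control with a pooled two-proportion Z-test.
    Includes hypergeometric pathway enrichment with cross-sample overlap
    detection, pathway-restricted recurrence screening of miRNAs and mRNAs,
    hierarchical clustering of miRNA biomarker panels, a negative-binomial
    synthetic-data generator with planted differentially repressed pathways,
    and readers and writers for wide count tables, scored interaction tables
    and GMT gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
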