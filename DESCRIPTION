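Package: panelcurate
Title: Amplicon Panel QC, Trimming, Concordance and Rule-Based Variant
    Curation for Targeted Diagnostic Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for targeted amplicon gene-panel
    diagnostics, built around a disorders-of-sex-development (DSD) panel of
    64 diagnostic genes. Provides amplicon-boundary-aware adapter
    read-through trimming for circularisation-based (HaloPlex-style)
    libraries, panel performance metrics (coverage distributions and
    uniformity, targeting efficiency, amplicon dropout analysis, per-gene
    diagnostic coverage), truth-versus-query variant callset concordance
    (sensitivity, false positive rate, ROC), a rule-based variant
    filtering and classification engine (pathogenic / likely pathogenic /
    VUS tiers with audit trails), cohort-level diagnostic-yield
    aggregation, and seeded simulators so every component is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
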