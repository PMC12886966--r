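Package: nddtrio
Title: Family-Based Whole-Genome Variant Prioritization for Neurodevelopmental Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested implementation of a family-based (trio/quad)
    whole-genome variant prioritization pipeline for neurodevelopmental
    disorder (NDD) cohorts. Provides trio-aware short-variant filtering and
    inheritance classification (de novo, X-linked, recessive, composite
    recessive), multi-caller structural-variant consensus and family-level
    merging, read-depth CNV segment filtering, cross-class compound
    heterozygote detection, candidate/suggestive variant categorization and
    diagnostic-yield statistics, KING-robust kinship QC, ACMG secondary
    findings screening, and an 8000-bp window delta-log-likelihood variant
    scoring protocol against a pluggable sequence scorer. A self-contained
    synthetic cohort generator with planted, truth-labelled events makes the
    whole pipeline testable without access to patient genomes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
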