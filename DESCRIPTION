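Package: marscan
Title: SNP-Array Karyotyping and Minimal Affected Region Discovery
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for SNP-array virtual karyotyping of tumor
    cohorts: paired or baseline log-R-ratio segmentation by recursive
    t-test splitting, five-state lesion classification (amplification and
    deletion with or without loss of heterozygosity, and acquired
    uniparental disomy), length/chromosome/cytoband filtering, cohort
    recurrence profiling with minimal-affected-region (MAR) discovery by
    sweep-line coverage, and calibrator-free TaqMan qPCR relative
    copy-number quantitation with replicate quality control. Includes a
    synthetic LRR/BAF cohort generator with known implanted lesions so the
    whole pipeline is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
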