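Package: ucre
Title: Annotation of Ultraconserved Non-Coding Elements as Candidate
    Cis-Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates ultraconserved non-coding elements (UCNEs) as candidate
    cis-regulatory elements from chromatin accessibility and histone-mark
    evidence, assigns their target genes with a basal-plus-extension
    regulatory-domain rule, prioritizes rare non-coding variants within them,
    and tests constraint-score depletion against a random genomic background
    with Kruskal-Wallis and Dunn post-hoc rank statistics. Ships a synthetic
    data generator with a planted truth table so the whole pipeline can be
    exercised end-to-end without protected cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
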