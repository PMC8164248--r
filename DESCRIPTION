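Package: cnvpop
Title: Consensus CNV Maps and Copy-Number Population Differentiation from Two-Caller SV Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for structural-variant call sets from two
    breakpoint callers: evidence-based filtering, per-sample consensus copy
    number variants (CNV) by call-set intersection, merging of CNV into CNV
    regions (CNVR) within populations and globally, sharing and private-region
    analysis across breeds and populations, cross-catalogue overlap comparison,
    read-depth normalization (RPKM with GC-content and mappability adjustment),
    and a V_ST copy-number population-differentiation scan with a
    99th-percentile outlier rule and gene annotation. Includes a synthetic
    cohort generator that emulates two-caller VCF output, per-region read
    counts with GC and mappability covariates, and planted
    population-differentiated loci, with ground truth for precision/recall
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    graphics,
    grDevices,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
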