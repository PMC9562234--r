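Package: ervpop
Title: Population Analysis of Insertionally Polymorphic Endogenous Retroviruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-scale analysis of insertionally polymorphic
    endogenous retrovirus (ERV) loci from short-read caller output. Applies
    stringent and relaxed filter cascades to insertion calls and to two
    deletion-call dialects, merges calls into a unified locus frame with
    GenomicRanges, builds per-individual presence/count matrices, computes
    per-species locus frequencies, calibrates the detection false-negative
    rate from ancestrally fixed loci, summarises family abundance with median
    identification ratios (MIR) at species and island resolution, classifies
    locus sharing across species, profiles chromosomal ERV density, and
    screens differentiated genomic regions for between-species frequency
    contrasts. Includes a synthetic-cohort generator with a coverage- and
    zygosity-dependent detection model so the full pipeline can be exercised
    and validated without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), GenomicRanges, SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, IRanges, rtracklayer,
    VariantAnnotation
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
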