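Package: asekit
Title: Allele-Specific Expression Analysis for Hybrid Cross Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for allele-resolved RNA-seq analysis in F1 hybrid
    systems: negative-binomial GLM differential expression in standard,
    per-allele and allele-by-condition interaction modes; classification
    of genes into biallelic, bi-to-monoallelic and mono-to-none categories;
    X-inactivation escapee detection; cross-clone and parent-of-origin
    consistency analysis; allelic DNA methylation quantification and
    differential methylation calling; peak-anchored aggregate contact
    analysis; allelic copy-number QC and single-cell allele frequencies.
    Includes a seeded synthetic-data generator with planted ground truth
    so every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
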