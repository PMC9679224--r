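Package: coldadapt
Title: Comparative Genomic Analysis of Cold-Adapted Yeasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative genomics of psychrophilic yeasts:
    assembly statistics from FASTA, composition-based protein flexibility
    scoring from annotated coding sequences, discovery and positional
    classification of small open reading frames (smORFs), gene-redundancy
    profiling, growth-curve parameter estimation (growth rate and optimal
    temperature for growth), cross-species ANOVA/Tukey comparisons of
    flexibility metrics with difference-vs-difference regressions, and a
    multigene neighbor-joining phylogeny workflow with generalized
    Jukes-Cantor distances and bootstrap supports. Includes a synthetic-data
    generator that plants genomes, smORFs, redundant gene families, growth
    curves and tree-evolved proteins with known truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
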