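Package: transannot
Title: Ortholog-Guided Annotation of De Novo Assembled Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable implementation of a de novo transcriptome
    processing pipeline for non-model organisms with a well-annotated
    close relative: genomic-contamination filtering of paired mRNA-seq
    reads by reference-alignment length, ortholog-guided full-length
    coding-sequence (CDS) annotation of assembled transcripts via
    six-frame translated local alignment, assembly contig statistics
    (N50, mean length), and quantitative concordance analysis of two
    protein annotation sets against a common reference proteome.
    Includes a fully seeded synthetic-data generator with a ground-truth
    manifest so every pipeline stage can be scored for precision and
    recall.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
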