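Package: cd4lag3
Title: Rule-Based Discrimination of CD4 and LAG-3 Family Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assigns CD4, CD4-1, CD4-2 or LAG-3 identity to CD4/LAG-3
    family genes of jawed vertebrates from the sequence and genomic
    features that discriminate the two lineages: degenerate
    cytoplasmic-tail motifs (the Cx(C/H) zinc clasp of CD4, the
    ITIM-like (F/Y)xxL(D/E) motif of LAG-3), intron phase of the
    D1-internal intron, the number of coding exons behind the
    transmembrane exon, Ig-like V/C2 ectodomain architecture,
    head-to-tail LAG-3/CD4 gene orientation, and thymus-dominant
    expression. Evidence is combined additively into a transparent
    per-gene report. A seeded synthetic-data generator plants all of
    these features into protein sequences, gene models, synteny and
    expression tables so that every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
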