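Package: primedesign
Title: Batch Long-Primer Design for Deleting and C-Terminally Tagging Yeast Genome Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Designs pFA6a-style long primers, in batch, for deleting (CDS,
    ncRNA, 3'UTR, tRNA) and C-terminally tagging (CDS) every annotated
    feature of a yeast genome. Reads a whole-genome FASTA and its GFF3
    annotation, extracts stranded flanking sequence with chromosome-end
    padding, appends the constant pFA6a priming tails, flags deletions that
    disrupt overlapping neighbour features, and writes a three-file
    tab-delimited primer database (header, primer table, check file). A
    seeded synthetic-genome generator with an independent brute-force primer
    oracle supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
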