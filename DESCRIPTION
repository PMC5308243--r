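Package: intronsig
Title: Intron Phase Architecture and Exon-Shuffling Signatures in
    Secretory Peptide Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the exon-intron architecture of genes
    encoding secreted peptide precursors, with a focus on scorpion venom
    components. Classifies every intron by phase (0/1/2), maps introns onto
    precursor protein coordinates (signal peptide, propeptide, mature
    peptide), and calls the exon-shuffling signature: a phase-1 intron near
    the signal-peptide cleavage site. Includes scaffold motif annotation
    (inhibitor cystine knot consensus with ring size and disulfide
    connectivity, CSab CX3C/CXC motifs), phase-frequency statistics with an
    exact multinomial test against literature reference proportions, a
    permutation test for boundary enrichment, an IUPAC promoter motif
    scanner with module-sharing scores, a fully ground-truthed synthetic
    gene generator, and text/SVG gene-structure diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
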