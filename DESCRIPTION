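Package: httscan
Title: Detection and Dating of Horizontal Transposon Transfer from
    Synonymous Divergence and Codon Usage Bias
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers horizontal transposon transfer (HTT) between species
    from coding-sequence statistics.  Reconstructs transposable-element
    copies from tabular homology hits, clusters them into cross-species
    families, and tests each family against the vertical-inheritance
    expectation set by a per-species-pair regression of synonymous
    divergence (Nei-Gojobori dS) on codon usage bias (Wright's effective
    number of codons).  Includes Kimura two-parameter intragenomic dating,
    molecular-clock dating of transfer events (T = k/2r), introgression
    discrimination from flanking sequence, genome-impact accounting, and a
    forward codon-sequence simulator that emits ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
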