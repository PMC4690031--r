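Package: codonbias
Title: Codon Usage Bias Analysis for Transcriptome Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome- and transcriptome-scale synonymous codon usage
    analysis of coding sequences (CDS): relative synonymous codon usage (RSCU),
    Wright's effective number of codons (ENC) with the expected-ENC null curve,
    the codon adaptation index (CAI) with explicit reference-set construction,
    positional GC composition and parity-rule-2 (PR2) bias coordinates,
    neutrality-plot statistics, correspondence analysis of gene-by-codon RSCU
    matrices, and chi-square determination of optimal codons from high- versus
    low-expression gene sets. Includes a synthetic CDS generator with
    controlled mutational GC pressure and translational selection so every
    stage of the pipeline can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    seqinr,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
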