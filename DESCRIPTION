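Package: outronscan
Title: Characterization of Spliced-Leader Trans-Spliced Genes from 5' Tag Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for characterizing spliced-leader (SL)
    trans-spliced genes from 5'-end sequencing tags. Classifies tags by SL
    prefix, maps and clusters their 5' ends, calls trans-splice acceptor
    sites (TAS) and transcription start sites (TSS) with open-chromatin
    corroboration, detects operons, classifies genes as trans-spliced or
    non-trans-spliced, estimates per-gene trans-splicing ratios, trains and
    applies PWM and maximum-entropy splice-site strength models, and performs
    windowed nucleotide-content and PWM-motif local enrichment tests
    (binomial against an intergenic background, then Fisher against control
    genes, with Benjamini-Hochberg correction). Ships a synthetic-genome
    simulator with full ground truth (operons, outrons, SL-prefixed vs capped
    tags at known mixing ratios, planted dinucleotide bias and motif
    occurrences) so every stage of the pipeline is testable against planted
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
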