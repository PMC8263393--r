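Package: trioregulome
Title: Prioritization of Noncoding Variants in Trio Genomes via a Tissue Regulome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a tissue-specific regulome interval mask from conservation,
    topologically associating domain (TAD), H3K27ac peak and validated enhancer
    tracks, and uses it to prioritize noncoding single-nucleotide and structural
    variants in trio genome-sequencing cohorts of congenital limb malformation.
    Implements rare/de novo/hemizygous-X filtering, cross-case proximity pairing,
    double-hit and in-trans screens, a loss-of-function double-hit gene screen,
    a structural-variant filter cascade with read-support escalation and
    inheritance exclusion, an ACMG evidence-combining classifier, and polyalanine
    repeat-tract measurement. Ships a seeded synthetic cohort generator with a
    truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
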