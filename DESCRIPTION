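Package: coevofam
Title: Co-Evolution Analysis of Two Gene Families Across a Species Panel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects co-evolution of two gene families across a panel of
    species by combining three complementary statistics: a Pearson
    chi-squared (and permutation) test of copy-number concordance, the
    correlation of percent-identity vectors to a shared reference species,
    and the mirror-tree correlation of inter-species distance matrices with
    a permutation null.  Also provides the supporting primitives: FASTA and
    multiple-alignment input, pairwise protein alignment with EMBOSS-style
    identity and similarity reporting, alignment-column conservation and
    positional motif scanning, repeat-interval masking, paralog-aware
    best-score read assignment with ex-aequo discarding, RPKM
    quantification and cross-species expression correlation, and a
    simulator of coupled gene-family evolution (shared duplication events
    and branch-rate multipliers along a species tree) so that every
    statistic has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Phylogenetics, SequenceMatching, Alignment, GeneExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
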