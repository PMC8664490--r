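Package: apeClock
Title: Branch-Specific Protein Substitution Rates in a Four-Taxon Ape Phylogeny
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing the molecular-clock null model of protein
    evolution on a four-taxon ape phylogeny (human, chimpanzee, gorilla,
    gibbon). Implements synteny-guided 1:1 ortholog calling from gene order
    and homology hits, reduction of family alignments to gap-free conserved
    blocks, classification of aligned columns into branch-specific and
    phylogenetically (in)consistent site patterns, Poisson-corrected
    branch-length and mean-tree computation, a bootstrap Z-test on the
    branch-length-aware Robinson-Foulds score against the mean tree, and a
    multinomial simulation null for detecting lineage-specific rate
    accelerations and decelerations. Includes a sequence simulator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Phylogenetics, SequenceAnalysis, Alignment, Software
RoxygenNote: 7.3.3
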