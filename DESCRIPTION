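Package: RabKit
Title: Annotation, Phylogenetic Classification, and Functional Profiling of
    Rab GTPase Families
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for genome-scale characterization of Rab GTPase families in
    ciliates and other protists. Identifies Rabs by scanning for the five
    Rab-family (RabF) motifs, discriminates Rabs from other small-GTPase
    families (Ras, Rho, Arf/Sar, Ran) by cross-family consensus scoring, and
    separates authentic Rabs from Rab-like proteins by testing C-terminal
    prenylation motifs. Predicts open reading frames under the ciliate nuclear
    genetic code (UAA/UAG = glutamine, UGA the sole stop), computes pairwise
    affine-gap alignments and reciprocal-best-hit orthologs, builds
    neighbor-joining trees with column-resampled bootstrap support and
    majority-rule consensus, and classifies family members as conserved,
    lineage-restricted, or divergent across multiple tree-building methods.
    Also includes stage-grid expression-peak detection for growth, starvation,
    and conjugation time courses, thresholded-mask colocalization
    quantification for two-channel images, seeded synthetic-data generators
    for every input type, and a packaged transcription of a published
    Tetrahymena Rab localization survey.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
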