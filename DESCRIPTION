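Package: chemannot
Title: Annotation and Expression Profiling of Chemosensory Gene Families
    in De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully tested implementation of a transcriptome
    gene-family annotation and expression-profiling pipeline for insect
    chemosensory genes (odorant, gustatory and ionotropic receptors,
    odorant-binding and chemosensory proteins, esterases and P450s).
    Provides paired-end read quality filtering, greedy identity
    clustering of redundant transcripts, six-frame ORF prediction with
    completeness classification, translated Smith-Waterman homology
    search with Karlin-Altschul E-values, iterative family annotation
    with family-specific ORF-length filters, pseudo-alignment plus EM
    abundance estimation yielding gene-level FPKM, heat-map matrices,
    and neighbor-joining bootstrap family trees. A ground-truthed
    synthetic transcriptome and read simulator supports end-to-end
    validation against planted gene families.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
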