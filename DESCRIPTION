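Package: MycoBarcode
Title: Barcode-Gap Evaluation of Fungal DNA Barcode Markers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating candidate DNA barcode loci in mushrooms and
    allied fungi. Implements preprocessing of ITS amplicons (conserved-motif
    trimming, 5.8S excision) and mitochondrial COI sequences (group-I intron
    localization and excision, degenerate-primer mapping and amplicon
    prediction), greedy percent-identity clustering of ITS sequences into
    alignment groups, progressive multiple alignment, Kimura two-parameter
    (K2P) corrected pairwise distances with a capping rule for extreme
    inter-specific divergences, neighbor-joining trees and reciprocal-monophyly
    assessment, per-species intra-/inter-specific divergence summaries and
    barcode-gap ratios for locus comparison, and a seeded sequence simulator
    with a dummy-sequence perturbation experiment for probing the robustness
    of the clustering step. A transcription of a published COI/ITS divergence
    table is included as an example data set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Phylogenetics, Alignment, Clustering, SequenceMatching
RoxygenNote: 7.3.3
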