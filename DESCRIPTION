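Package: cellumod
Title: Comparative Sequence Analysis of Modular GH9 Cellulases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative in-silico analysis of modular glycosyl
    hydrolase family 9 (GH9) cellulases: a PROSITE pattern parser and scanner,
    annotation of the conserved catalytic Regions I-III (including the DAGD
    motif and the algal-specific Region II insertion), composition-based
    segmentation of proteins into catalytic domains, P/S/T-classified linkers
    and cysteine-rich carbohydrate-binding modules, percent-identity matrices
    with neighbor-joining trees and bootstrap support, and multi-reference-gene
    qPCR expression analysis (geNorm stability, efficiency-corrected normalized
    relative quantities, two-group tests). A synthetic-data generator emits
    modular cellulase-like proteins, tree-evolved families and Cq tables with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
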