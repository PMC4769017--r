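Package: mapkloop
Title: MAPK Activation-Loop Motif Discovery and Molecular-Evolution
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-scale discovery and classification of mitogen-activated
    protein kinase (MAPK) activation-loop motifs in protein sequences. A
    PROSITE-syntax pattern engine locates the conserved kinase-domain
    anchors (H-R-D-L-K-P-N and T-R-W-Y-R-A-P) flanking the activation
    segment, extracts the T-x-Y phospho-acceptor triplet between them, and
    classifies triplets against a catalog of canonical and novel fungal
    motifs with per-species and per-group summaries. Molecular-evolution
    statistics for amino-acid alignments include Tajima's test of
    neutrality (pairwise deletion) and Tajima's relative-rate test
    (complete deletion), plus p-distances and a neighbor-joining utility.
    Seeded synthetic generators produce kinase-like proteins with planted
    anchors and alignments with controlled site structure so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
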