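Package: CellTypeTrees
Title: Cell-Type Trees from Histone Modification ChIP-Seq Peaks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs cell-type trees from histone-modification ChIP-Seq
    peak lists. Peak libraries are coded into binary presence/absence
    matrices using either fixed-size genome bins (windowing) or the
    connected components of the interval graph over all peaks (overlap
    representation), optionally averaged into per-cell-type profiles.
    Pairwise Hamming or Manhattan distances feed Neighbor-Joining tree
    inference; trees are scored with the star-shape ratio (SR) and percent
    deviation (PD) statistics, replicate clades can be collapsed, and
    gain/loss patterns of marks along differentiation paths are tabulated
    and exported as BED. A synthetic peak simulator with known ground-truth
    trees makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
biocViews: Epigenetics, ChIPSeq, Phylogenetics, HistoneModification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
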