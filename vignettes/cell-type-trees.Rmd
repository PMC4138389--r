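---
title: "Inferring cell-type trees from histone-mark peak lists"
author: "CellTypeTrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-type trees from histone-mark peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(CellTypeTrees))
```

## The problem and the model

During differentiation a cell's genome is essentially fixed while its
epigenome changes: histone modifications such as H3K4me3 (activating) or
H3K27me3 (repressive) are gained and lost region by region.  If those
gains and losses accumulate along the paths of differentiation, then
genome-wide ChIP-Seq peak lists from many cell types carry a tree-like
signal, and distance-based phylogenetic machinery can recover a
*cell-type tree*: a tree whose leaves are assayed cell types (or
individual replicate libraries) and whose edges represent
differentiation of one type from cells of another.

The working model is deliberately minimal: each genomic region carries a
binary state (mark present/absent) per cell type, and states flip
independently per region along each edge of the tree.  Independence
across regions is a simplification — it ignores co-regulated domains —
but it makes the representation a vector of binary characters, for which
Hamming-type distances and Neighbor-Joining (NJ) are natural tools.  No
substitution model is fitted; nothing here assumes a molecular clock.

## Representations

Starting from per-library peak lists (ENCODE narrowPeak/broadPeak or
plain BED; coordinates are treated as 0-based half-open throughout and
converted to the 1-based `GRanges` convention internally), the package
codes libraries into a features-by-libraries 0/1 matrix in two ways.

**Windowing** (`windowMatrix`): the genome is cut into fixed bins and a
bin is coded 1 for a library when any of its peaks overlaps the bin.
The 200 bp default approximates a single nucleosome (147 bp of wrapped
DNA plus linker), so one bin is roughly one histone's state.  Overlap —
rather than containment — is used for peaks straddling a bin boundary,
so a short peak across a boundary lights both bins; containment would
silently drop such peaks.  Each library's coding is independent of the
others; all-zero bins are never materialised (they cannot change a
Hamming distance, and materialising them would make matrices
genome-sized).

**Overlap** (`overlapMatrix`): all peaks of all libraries are pooled and
the *interesting regions* are the connected components of their interval
graph — maximal runs of transitively overlapping peaks, computed by a
single linear sweep over the sorted pooled peaks.  One column per
region, coded 1 for a library intersecting it.  This joint coding
absorbs boundary noise (peak ends are the least reproducible part of a
peak call) at the cost of detail, and by construction every region is
backed by at least one peak, so the all-zero column does not exist.
Two touching half-open intervals (`[0,10)` and `[10,20)`) do *not*
overlap and stay in separate components; the choice is arbitrary at the
base-pair scale but must be fixed for the representation to be unique.

**Profiles** (`profileMatrix`): replicate columns of one cell type are
averaged, giving values in {0, 1/r, ..., 1}; with two replicates, 0.5
flags replicate disagreement.  Profile distances are Manhattan sums,
which reduce to Hamming on 0/1 profiles.

Two column filters support replicate analyses.  *Masking*
(`maskNearConstantColumns`) drops every feature in which at most one
library deviates from the rest — constant features carry no signal, and
single-deviant features are indistinguishable from one-library noise;
the filter needs at least three libraries and is idempotent.  *Consensus*
(`consensusByCellType`) keeps only features where every listed cell
type's replicates agree, the precondition for the pattern analyses
below.

## Distances, trees and tree statistics

Pairwise distances are raw Hamming counts (binary matrices) or Manhattan
sums (profiles); they are not normalised by feature count by default, so
values are comparable only within one matrix (pass `normalize = TRUE`
for cross-dataset work).  Trees are inferred with Saitou–Nei
Neighbor-Joining (`neighborJoining`, delegating to `ape::nj`).  NJ can
emit slightly negative branch lengths on noisy input; these are clamped
to zero at assignment and counted (`attr(tree, "clampCount")`), and all
statistics below use the clamped lengths.

Two statistics summarise how much to trust a tree:

* **SR** (`srRatio`) = (sum of leaf-incident edge lengths) / (total edge
  length) ∈ [0, 1].  SR near 1 means the tree is effectively a star —
  almost all length sits on pendant edges, as happens when within-type
  noise dominates.  "Leaf edge" means any edge incident to a degree-1
  node of the unrooted tree, so the statistic does not depend on an
  arbitrary rooting; it is invariant under uniform rescaling.
* **PD** (`percentDeviation`) = 100 × mean over unordered leaf pairs
  with positive matrix distance of |tree-path distance − matrix
  distance| / matrix distance.  PD = 0 means the matrix is exactly
  additive; a few percent means the data are tree-like.  Averaging
  relative errors (rather than summing, or normalising by the matrix
  total) was a genuinely open choice; pairs at distance zero (identical
  libraries) are excluded because their relative error is undefined.
  The definition is printed in the CLI output header so downstream
  readers see exactly what was computed.

Replicates of one type are expected to form cherries;
`collapseReplicateClades` replaces every maximal subtree whose leaves
all belong to one type by its attachment node, keeping the attachment
edge length — the collapsed leaf then represents the type's population
rather than either noisy replicate.  Purity is evaluated on the
*unrooted* tree: a pure component can span the arbitrary basal
trifurcation of the stored representation, so the implementation reroots
at a leaf outside the class under consideration before searching for
pure clades (a rooted-view search provably misses cherries attached at
the basal node).  Non-monophyletic replicate sets are collapsed per
maximal pure subtree with a warning and yield duplicate leaf labels.
`groupPurityStats` quantifies clustering quality per group label as the
leaf counts of the two largest single-edge-cut subtrees containing only
that group's leaves.

## Differentiation-path patterns

Given an ordered path of cell types (say stem-cell culture days D0, D2,
D5, D9, D14), `pathPatternCounts` forms, for every replicate-unambiguous
feature, the 0/1 pattern along the path and tabulates the patterns; the
all-zero pattern is excluded (in the overlap representation it cannot
occur on the full library set, and excluding it keeps the convention
stable when the matrix was built on a superset of libraries).
`selectGroupSpecificRegions` finds features all-1 inside a chosen
library group and all-0 outside (and the mirror image), allowing at most
`maxErrors` deviating libraries on each side — with the default of one
error per side this is the selection used to find, e.g., stem-cell
specific marked regions.  `regionsMatchingPattern` exports the features
behind any one pattern as BED for external enrichment tools.

## The synthetic-data generator

`simulateGainLoss` + `emitPeakLibraries` generate data the pipeline can
be validated against: a uniformly random labelled bifurcating topology;
per-region Bernoulli(0.5) root states; independent per-edge, per-region
flips with per-edge probabilities drawn uniformly from [0.02, 0.1];
per-replicate flips at 0.01; regions of 1 kb separated by 500 bp gaps on
one synthetic chromosome; emitted peak endpoints jittered by up to
100 bp; and per-peak −log10 p-values drawn above the conventional
threshold of 10 with probability 0.9 (shifted exponential tail, rate
0.2) and uniform below it otherwise, so significance filtering can be
exercised deterministically.

The defaults are the package's reference study conditions.  The
replicate and edge noise levels describe a medium-noise regime in which
replicates differ at about 2% of regions while adjacent cell types
differ at 4–20% — the regime in which replicate cherries form but the
tree is not trivially recoverable.  Region geometry is the scale of
promoter-mark peaks (about 1 kb); the jitter bound of 100 bp is large
relative to a 200 bp bin but below half the gap, which guarantees
jittered peaks from adjacent truth regions can never merge, so the
overlap representation's region count is predictable.  Everything is
reproducible from one integer seed (emission uses seed + 1 so truth and
emission draws do not interleave).

What the generator does *not* emulate: correlated gains/losses across
neighbouring regions, peak-caller biases beyond boundary jitter,
signal-strength variation, copy-number or mappability artefacts, and
inter-individual variation between biological replicates beyond i.i.d.
flips.  Passing the recovery tests therefore shows the pipeline is
correct and well-behaved under its own model, not that real peak data
meet that model.

## Numerical and degenerate-input choices

* Filtering thresholds are inclusive (`negLogP >= threshold`).
* Distance matrices must be symmetric (tolerance 1e-8) with zero
  diagonal; fewer than three taxa is an error for NJ.
* `srRatio` is an error on a zero-total-length tree (0/0).
* `percentDeviation` is an error when no pair has positive distance.
* Masking requires ≥ 3 libraries; an all-near-constant matrix returns an
  empty matrix with a warning rather than an error.
* Feature order is genomic (chromosome lexicographic via
  `sortSeqlevels`, then start), making serialized matrices and all
  derived objects byte-deterministic.
* NJ tie-breaking follows `ape::nj`'s deterministic implementation.

## Validation and problem sizes

The test suite validates each stage against an independent oracle:
interesting regions against a brute-force interval graph (pairwise
overlap tests + graph components) on random instances of up to 20
libraries × 200 peaks; NJ against generating trees of random additive
matrices (5–30 taxa) where consistency demands exact topology recovery
(Robinson–Foulds 0) and PD ≈ 0; Robinson–Foulds against explicit split
enumeration; and the full pipeline against simulation ground truth at
the reference conditions (12 types × 2 replicates, 5000 regions), where
a 20-seed pilot at those conditions recovered the exact collapsed
topology in 18 of 20 seeds — the acceptance bar is frozen at ≥ 18/20,
and the residual failures are single-split NJ errors (RF = 2) under the
prescribed noise, not replicate-grouping failures.  These sizes keep the
whole suite in the minutes range on one CPU while leaving each test
statistically meaningful.

## Limitations

Distances ignore any model of gain/loss rates, so branch lengths are
differences, not time; ancestral (internal-node) states are deliberately
not reconstructed; maximum parsimony and likelihood methods are out of
scope, as are peak calling, IDR analysis and enrichment testing —
peak lists come in, trees, statistics, tables and BED files go out.
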