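#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList granges seqnames start end
#'   width reduce findOverlaps
#' @importFrom GenomeInfoDb seqlevels seqlengths sortSeqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#'   colData rowRanges<- colData<-
NULL

setOldClass("phylo")

# each list element sorted by (chrom, start, end), relative to its own
# seqlevels order; vectorised over the whole list
.grlIsSorted <- function(grl) {
    ul <- unlist(grl, use.names = FALSE)
    n <- length(ul)
    if (n < 2L) return(TRUE)
    g <- rep.int(seq_along(grl), lengths(grl))
    i <- seq_len(n - 1L); j <- i + 1L
    ch <- as.integer(seqnames(ul)); s <- start(ul); e <- end(ul)
    ok <- ch[i] < ch[j] |
        (ch[i] == ch[j] & (s[i] < s[j] | (s[i] == s[j] & e[i] <= e[j])))
    all(ok[g[i] == g[j]])
}

#' PeakLibrarySet: a collection of ChIP-Seq peak libraries
#'
#' Holds one sorted \link[GenomicRanges]{GRanges} of peaks per ChIP-Seq
#' library together with the manifest that binds each library to its cell
#' type, replicate index and group label.  Peak coordinates are stored
#' 1-based closed (the \pkg{GenomicRanges} convention); the reader converts
#' from BED 0-based half-open input and the writers convert back.  Each
#' peak may carry a \code{negLogP} metadata column (the \eqn{-\log_{10}}
#' p-value reported by the peak caller, \code{NA} when the input dialect
#' has no score column).
#'
#' @slot peaks A \link[GenomicRanges]{GRangesList}, one element per library,
#'   named by library id, each sorted by (chrom, start, end).
#' @slot manifest A \code{data.frame} with columns \code{library_id},
#'   \code{cell_type}, \code{replicate}, \code{group} (and optionally
#'   \code{path}), one row per library, in the same order as \code{peaks}.
#'
#' @seealso \code{\link{loadPeakLibraries}}, \code{\link{readPeakFile}},
#'   \code{\link{overlapMatrix}}, \code{\link{windowMatrix}}
#' @export
setClass("PeakLibrarySet",
    slots = c(peaks = "GRangesList", manifest = "data.frame"))

setValidity("PeakLibrarySet", function(object) {
    m <- object@manifest
    msgs <- character()
    need <- c("library_id", "cell_type", "replicate", "group")
    if (!all(need %in% names(m)))
        return(paste("manifest must have columns:", paste(need, collapse = ", ")))
    if (length(object@peaks) != nrow(m))
        msgs <- c(msgs, "one manifest row is required per peak library")
    if (anyDuplicated(m$library_id))
        msgs <- c(msgs, "library_id values must be unique")
    if (!identical(names(object@peaks), as.character(m$library_id)))
        msgs <- c(msgs, "names(peaks) must equal manifest$library_id, in order")
    if (any(m$replicate < 1L))
        msgs <- c(msgs, "replicate indices must be positive")
    if (!.grlIsSorted(object@peaks))
        msgs <- c(msgs, "peaks must be sorted within each library")
    if (length(msgs)) msgs else TRUE
})

#' Construct a PeakLibrarySet
#'
#' @param peaks A named \link[GenomicRanges]{GRangesList} of peak intervals,
#'   or a plain list of \code{GRanges} (coerced).  Unsorted elements are
#'   sorted; within-library overlapping peaks are reported with a warning
#'   but kept.
#' @param manifest A \code{data.frame} with columns \code{library_id},
#'   \code{cell_type}, \code{replicate}, \code{group}.
#' @return A \linkS4class{PeakLibrarySet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300))
#' m <- data.frame(library_id = "L1", cell_type = "A",
#'                 replicate = 1L, group = "G")
#' PeakLibrarySet(list(L1 = gr), m)
#' @export
PeakLibrarySet <- function(peaks, manifest) {
    if (!is(peaks, "GRangesList"))
        peaks <- GRangesList(peaks)
    # lexicographic chromosome order, independent of input encounter order
    peaks <- sort(sortSeqlevels(peaks))
    hasOvl <- lengths(IRanges::reduce(peaks, min.gapwidth = 0L)) <
        lengths(peaks)
    if (any(hasOvl))
        warning("overlapping peaks within libraries: ",
                paste(names(peaks)[hasOvl], collapse = ", "))
    manifest$library_id <- as.character(manifest$library_id)
    manifest$replicate <- as.integer(manifest$replicate)
    if (is.null(names(peaks)))
        names(peaks) <- manifest$library_id
    new("PeakLibrarySet", peaks = peaks, manifest = manifest)
}

#' @importFrom S4Vectors endoapply
NULL

#' MarkMatrix: binary presence/absence of a mark over genomic features
#'
#' A \link[SummarizedExperiment]{RangedSummarizedExperiment} whose rows are
#' genomic feature columns of the representation (fixed-size bins or
#' interesting regions) and whose columns are ChIP-Seq libraries.  The
#' single assay, \code{"presence"}, holds 0/1 integers: 1 when the library
#' has at least one peak intersecting the feature.  \code{colData} carries
#' the manifest fields (\code{cell_type}, \code{replicate}, \code{group});
#' \code{metadata()$representation} records whether the matrix came from
#' windowing or overlap coding, and \code{metadata()$binSize} the bin size
#' where applicable.
#'
#' Note the orientation: the field's usual description of these data puts
#' libraries in rows and features in columns; this container transposes
#' that so features carry coordinates in \code{rowRanges}, as is standard
#' for \code{SummarizedExperiment}.  \code{\link{presenceMatrix}} returns
#' the libraries-by-features view.
#'
#' @seealso \code{\link{overlapMatrix}}, \code{\link{windowMatrix}},
#'   \code{\link{hammingDistance}}, \code{\link{maskNearConstantColumns}}
#' @export
setClass("MarkMatrix", contains = "RangedSummarizedExperiment")

setValidity("MarkMatrix", function(object) {
    if (!"presence" %in% SummarizedExperiment::assayNames(object))
        return("assay 'presence' is required")
    a <- assay(object, "presence")
    if (length(a) && !all(a %in% c(0L, 1L)))
        return("assay 'presence' must contain only 0/1 values")
    if (is.unsorted(rowRanges(object)))
        return("feature rows must be sorted by (chrom, start)")
    TRUE
})

#' MarkProfile: per-cell-type replicate-averaged mark profile
#'
#' Like \linkS4class{MarkMatrix} but with one column per cell type and a
#' \code{"profile"} assay of values in [0,1]: each entry is the fraction of
#' that cell type's replicates showing a peak in the feature, so values are
#' multiples of 1/r for r replicates (0, 0.5, 1 with two replicates).
#'
#' @seealso \code{\link{profileMatrix}}, \code{\link{manhattanDistance}}
#' @export
setClass("MarkProfile", contains = "RangedSummarizedExperiment")

setValidity("MarkProfile", function(object) {
    if (!"profile" %in% SummarizedExperiment::assayNames(object))
        return("assay 'profile' is required")
    a <- assay(object, "profile")
    if (length(a) && (min(a) < 0 || max(a) > 1))
        return("profile values must lie in [0, 1]")
    TRUE
})

#' SimulationConfig: parameters of the gain/loss peak simulator
#'
#' Describes a simulation in which binary region states evolve along a
#' random bifurcating cell-type tree by independent per-edge flips, are
#' perturbed per replicate, and are emitted as peak libraries with jittered
#' boundaries and per-peak significance scores.
#'
#' The defaults encode the reference study conditions used throughout the
#' package's validation: 12 cell types with 2 replicates each, 5000
#' regions, per-edge flip probabilities drawn uniformly in
#' [\code{edgeFlipMin}, \code{edgeFlipMax}] = [0.02, 0.1], and a replicate
#' flip probability of 0.01.
#'
#' @slot nCellTypes Number of leaf cell types (>= 3).
#' @slot replicatesPerType Replicates emitted per cell type (>= 1).
#' @slot nRegions Number of ground-truth regions.
#' @slot rootPresenceProb Probability a region carries the mark at the root.
#' @slot edgeFlipMin,edgeFlipMax Range of the per-edge, per-region state
#'   flip probability; each edge's probability is drawn uniformly in this
#'   range (set both equal for a fixed rate).  Must lie in [0, 0.5).
#' @slot replicateFlipProb Per-replicate, per-region flip probability in
#'   [0, 0.5).
#' @slot gainProb,lossProb Optional asymmetric per-edge rates; when not
#'   \code{NA} they override the symmetric edge flip range (gain: 0 to 1,
#'   loss: 1 to 0).
#' @slot regionLengthBp,gapBp Length of each truth region and of the gap
#'   separating consecutive regions, in bp.
#' @slot boundaryJitterBp Maximum absolute jitter applied to each emitted
#'   peak endpoint; must be < gapBp/2 so jitter cannot merge adjacent
#'   truth regions.
#' @slot significantFraction Fraction of emitted peaks whose score is
#'   drawn above the conventional -log10 p-value threshold of 10.
#' @slot seed Integer seed; all outputs are reproducible from it.
#'
#' @seealso \code{\link{simulationConfig}}, \code{\link{simulateGainLoss}},
#'   \code{\link{emitPeakLibraries}}, \code{\link{recoveryHarness}}
#' @export
setClass("SimulationConfig",
    slots = c(nCellTypes = "integer", replicatesPerType = "integer",
              nRegions = "integer", rootPresenceProb = "numeric",
              edgeFlipMin = "numeric", edgeFlipMax = "numeric",
              replicateFlipProb = "numeric",
              gainProb = "numeric", lossProb = "numeric",
              regionLengthBp = "integer", gapBp = "integer",
              boundaryJitterBp = "integer",
              significantFraction = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msgs <- character()
    if (object@nCellTypes < 3L) msgs <- c(msgs, "nCellTypes must be >= 3")
    if (object@replicatesPerType < 1L)
        msgs <- c(msgs, "replicatesPerType must be >= 1")
    if (object@nRegions < 1L) msgs <- c(msgs, "nRegions must be positive")
    if (object@rootPresenceProb < 0 || object@rootPresenceProb > 1)
        msgs <- c(msgs, "rootPresenceProb must lie in [0, 1]")
    okp <- function(p) all(p >= 0 & p < 0.5)
    if (!okp(c(object@edgeFlipMin, object@edgeFlipMax)))
        msgs <- c(msgs, "edge flip probabilities must lie in [0, 0.5)")
    if (object@edgeFlipMin > object@edgeFlipMax)
        msgs <- c(msgs, "edgeFlipMin must not exceed edgeFlipMax")
    if (!okp(object@replicateFlipProb))
        msgs <- c(msgs, "replicateFlipProb must lie in [0, 0.5)")
    if (!is.na(object@gainProb) && (object@gainProb < 0 || object@gainProb >= 0.5))
        msgs <- c(msgs, "gainProb must lie in [0, 0.5)")
    if (!is.na(object@lossProb) && (object@lossProb < 0 || object@lossProb >= 0.5))
        msgs <- c(msgs, "lossProb must lie in [0, 0.5)")
    if (xor(is.na(object@gainProb), is.na(object@lossProb)))
        msgs <- c(msgs, "gainProb and lossProb must be set together")
    if (object@regionLengthBp < 1L || object@gapBp < 1L)
        msgs <- c(msgs, "regionLengthBp and gapBp must be positive")
    if (object@boundaryJitterBp < 0L)
        msgs <- c(msgs, "boundaryJitterBp must be non-negative")
    if (object@boundaryJitterBp >= object@gapBp / 2)
        msgs <- c(msgs, "boundaryJitterBp must be < gapBp/2")
    if (object@significantFraction < 0 || object@significantFraction > 1)
        msgs <- c(msgs, "significantFraction must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' GainLossTruth: ground truth of a simulated differentiation history
#'
#' The record produced by \code{\link{simulateGainLoss}}: the true
#' cell-type tree, the 0/1 state of every region at every tree node, and
#' the genomic coordinates assigned to the regions.
#'
#' @slot tree The true rooted bifurcating cell-type tree (\code{phylo});
#'   leaf labels are the cell-type names.
#' @slot nodeStates Integer 0/1 matrix, one row per tree node (tips first,
#'   in \code{tree$tip.label} order, then internal nodes in \pkg{ape}
#'   numbering), one column per region.
#' @slot regions \link[GenomicRanges]{GRanges} of the truth regions, in
#'   region order.
#' @slot edgeFlipProb Numeric vector of per-edge flip probabilities, in
#'   \code{tree$edge} order (symmetric model), or the per-edge gain
#'   probabilities when the asymmetric model is used.
#' @export
setClass("GainLossTruth",
    slots = c(tree = "phylo", nodeStates = "matrix", regions = "GRanges",
              edgeFlipProb = "numeric"))

setValidity("GainLossTruth", function(object) {
    msgs <- character()
    ntot <- length(object@tree$tip.label) + object@tree$Nnode
    if (nrow(object@nodeStates) != ntot)
        msgs <- c(msgs, "nodeStates needs one row per tree node")
    if (ncol(object@nodeStates) != length(object@regions))
        msgs <- c(msgs, "nodeStates needs one column per region")
    if (length(object@nodeStates) &&
        !all(object@nodeStates %in% c(0L, 1L)))
        msgs <- c(msgs, "nodeStates must be 0/1")
    if (length(msgs)) msgs else TRUE
})
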