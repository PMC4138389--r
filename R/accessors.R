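#' @rdname PeakLibrarySet-accessors
#' @name PeakLibrarySet-accessors
#' @title Accessors for PeakLibrarySet objects
#' @description Extract the manifest, library identifiers, cell types,
#'   group labels or peak ranges from a \linkS4class{PeakLibrarySet}.
#' @param x A \linkS4class{PeakLibrarySet}.
#' @param library Optional library id; when given, \code{peakRanges}
#'   returns that library's \code{GRanges} instead of the full
#'   \code{GRangesList}.
#' @return \code{manifest}: a \code{data.frame}; \code{libraryIds},
#'   \code{cellTypes}, \code{groups}: character vectors, one entry per
#'   library; \code{peakRanges}: a \code{GRangesList} or \code{GRanges};
#'   \code{nLibraries}: an integer.
NULL

#' @rdname PeakLibrarySet-accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname PeakLibrarySet-accessors
#' @export
setMethod("manifest", "PeakLibrarySet", function(x) x@manifest)

#' @rdname PeakLibrarySet-accessors
#' @export
setGeneric("libraryIds", function(x) standardGeneric("libraryIds"))
#' @rdname PeakLibrarySet-accessors
#' @export
setMethod("libraryIds", "PeakLibrarySet",
    function(x) x@manifest$library_id)

#' @rdname PeakLibrarySet-accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
#' @rdname PeakLibrarySet-accessors
#' @export
setMethod("cellTypes", "PeakLibrarySet",
    function(x) as.character(x@manifest$cell_type))

#' @rdname PeakLibrarySet-accessors
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))
#' @rdname PeakLibrarySet-accessors
#' @export
setMethod("groups", "PeakLibrarySet",
    function(x) as.character(x@manifest$group))

#' @rdname PeakLibrarySet-accessors
#' @export
setGeneric("peakRanges", function(x, library = NULL)
    standardGeneric("peakRanges"))
#' @rdname PeakLibrarySet-accessors
#' @export
setMethod("peakRanges", "PeakLibrarySet", function(x, library = NULL) {
    if (is.null(library)) return(x@peaks)
    if (!library %in% names(x@peaks))
        stop("unknown library id: ", library)
    x@peaks[[library]]
})

#' @rdname PeakLibrarySet-accessors
#' @export
setGeneric("nLibraries", function(x) standardGeneric("nLibraries"))
#' @rdname PeakLibrarySet-accessors
#' @export
setMethod("nLibraries", "PeakLibrarySet", function(x) length(x@peaks))

setMethod("show", "PeakLibrarySet", function(object) {
    m <- object@manifest
    cat(sprintf("PeakLibrarySet with %d libraries (%d cell types, %d groups)\n",
                nrow(m), length(unique(m$cell_type)),
                length(unique(m$group))))
    n <- lengths(object@peaks)
    cat(sprintf("  peaks per library: min %d / median %.0f / max %d\n",
                if (length(n)) min(n) else 0L, stats::median(n),
                if (length(n)) max(n) else 0L))
    ids <- m$library_id
    if (length(ids) > 6) ids <- c(ids[1:5], "...")
    cat("  libraries:", paste(ids, collapse = ", "), "\n")
})

#' Libraries-by-features view of a MarkMatrix
#'
#' Returns the binary matrix in the orientation used by the distance and
#' pattern machinery: one row per library, one column per genomic feature
#' (named \code{chrom:start-end} with BED half-open coordinates).
#'
#' @param x A \linkS4class{MarkMatrix}.
#' @return An integer 0/1 matrix with library ids as row names.
#' @examples
#' pls <- examplePeakLibrarySet()
#' presenceMatrix(overlapMatrix(pls))
#' @export
presenceMatrix <- function(x) {
    stopifnot(is(x, "MarkMatrix"))
    t(assay(x, "presence"))
}

#' Feature identifiers of a representation matrix
#'
#' @param x A \linkS4class{MarkMatrix} or \linkS4class{MarkProfile}.
#' @return Character vector \code{chrom:start-end} in BED (0-based,
#'   half-open) coordinates, one per feature row.
#' @export
featureIds <- function(x) {
    gr <- rowRanges(x)
    sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr) - 1L, end(gr))
}

setMethod("show", "MarkMatrix", function(object) {
    md <- metadata(object)
    cat(sprintf("MarkMatrix (%s representation): %d features x %d libraries\n",
                if (is.null(md$representation)) "?" else md$representation,
                nrow(object), ncol(object)))
    if (!is.null(md$binSize))
        cat(sprintf("  bin size: %d bp\n", md$binSize))
    a <- assay(object, "presence")
    if (length(a))
        cat(sprintf("  fill: %.1f%% ones\n", 100 * mean(a)))
})

setMethod("show", "MarkProfile", function(object) {
    cat(sprintf("MarkProfile: %d features x %d cell types\n",
                nrow(object), ncol(object)))
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  %d cell types x %d replicates, %d regions\n",
                object@nCellTypes, object@replicatesPerType,
                object@nRegions))
    if (is.na(object@gainProb))
        cat(sprintf("  edge flip prob in [%.3g, %.3g], replicate flip %.3g\n",
                    object@edgeFlipMin, object@edgeFlipMax,
                    object@replicateFlipProb))
    else
        cat(sprintf("  gain %.3g / loss %.3g per edge, replicate flip %.3g\n",
                    object@gainProb, object@lossProb,
                    object@replicateFlipProb))
    cat(sprintf("  region %d bp, gap %d bp, jitter <= %d bp, seed %d\n",
                object@regionLengthBp, object@gapBp,
                object@boundaryJitterBp, object@seed))
})

setMethod("show", "GainLossTruth", function(object) {
    cat(sprintf("GainLossTruth: %d cell types, %d regions\n",
                length(object@tree$tip.label), length(object@regions)))
    cat(sprintf("  marked fraction at leaves: %.3f\n",
                mean(object@nodeStates[seq_along(object@tree$tip.label), ])))
})

#' @rdname GainLossTruth-accessors
#' @name GainLossTruth-accessors
#' @title Accessors for GainLossTruth objects
#' @param x A \linkS4class{GainLossTruth}.
#' @return \code{trueTree}: a \code{phylo}; \code{nodeStates}: an integer
#'   0/1 matrix (tree nodes by regions); \code{truthRegions}: a
#'   \code{GRanges}.
NULL

#' @rdname GainLossTruth-accessors
#' @export
trueTree <- function(x) { stopifnot(is(x, "GainLossTruth")); x@tree }
#' @rdname GainLossTruth-accessors
#' @export
nodeStates <- function(x) { stopifnot(is(x, "GainLossTruth")); x@nodeStates }
#' @rdname GainLossTruth-accessors
#' @export
truthRegions <- function(x) { stopifnot(is(x, "GainLossTruth")); x@regions }
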