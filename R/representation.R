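#' Interesting regions: connected components of the peak interval graph
#'
#' Pools the peaks of all libraries and returns one maximal interval per
#' connected component of their interval graph, i.e. per maximal run of
#' transitively overlapping peaks.  Each region spans from the smallest
#' left endpoint to the largest right endpoint of its component.  The
#' result is unique for a given input, disjoint, and sorted.  Peaks that
#' merely touch under the half-open convention (BED \code{[0,10)} and
#' \code{[10,20)}) do not overlap and stay in separate regions.
#'
#' The computation is a single left-to-right sweep per chromosome over the
#' sorted pooled peaks, linear in the total number of peaks.
#'
#' @param x A \linkS4class{PeakLibrarySet}, or directly a
#'   \code{GRangesList} / pooled \code{GRanges} of peaks (the regions
#'   depend only on the pooled peaks).
#' @return A sorted \code{GRanges} of disjoint regions.
#' @examples
#' pls <- examplePeakLibrarySet()
#' interestingRegions(pls)
#' @export
interestingRegions <- function(x) {
    all <- if (is(x, "PeakLibrarySet")) unlist(x@peaks, use.names = FALSE)
           else if (is(x, "GRangesList")) unlist(x, use.names = FALSE)
           else if (is(x, "GRanges")) x
           else stop("x must be a PeakLibrarySet, GRangesList or GRanges")
    all <- sortSeqlevels(all)
    if (!length(all))
        return(sort(GRanges()))
    # closed-coordinate adjacency (gap 0) corresponds to touching
    # half-open intervals, which must not merge
    sort(reduce(granges(all), min.gapwidth = 0L, ignore.strand = TRUE))
}

.markColData <- function(m) {
    DataFrame(cell_type = as.character(m$cell_type),
              replicate = as.integer(m$replicate),
              group = as.character(m$group),
              row.names = m$library_id)
}

.newMarkMatrix <- function(presence, regions, man, representation,
                           binSize = NULL) {
    rownames(presence) <- NULL
    se <- SummarizedExperiment(
        assays = list(presence = presence),
        rowRanges = regions,
        colData = .markColData(man))
    mm <- new("MarkMatrix", se)
    metadata(mm)$representation <- representation
    if (!is.null(binSize)) metadata(mm)$binSize <- as.integer(binSize)
    mm
}

#' Overlap representation of a set of peak libraries
#'
#' Codes each library against the \code{\link{interestingRegions}} of the
#' whole set: entry 1 when the library has at least one peak intersecting
#' the region, else 0.  Because every region arises from at least one
#' peak, every feature row has at least one 1.  The coding is joint: the
#' region universe depends on all libraries at once (adding a library can
#' merge regions), unlike \code{\link{windowMatrix}}.
#'
#' @param x A \linkS4class{PeakLibrarySet}.
#' @return A \linkS4class{MarkMatrix} (regions by libraries).
#' @examples
#' mm <- overlapMatrix(examplePeakLibrarySet())
#' presenceMatrix(mm)
#' @export
overlapMatrix <- function(x) {
    stopifnot(is(x, "PeakLibrarySet"))
    regions <- interestingRegions(x)
    presence <- vapply(seq_along(x@peaks), function(i)
        as.integer(IRanges::overlapsAny(regions, x@peaks[[i]])),
        integer(length(regions)))
    if (length(regions) == 0L)
        presence <- matrix(integer(0), 0L, length(x@peaks))
    if (is.null(dim(presence)))
        presence <- matrix(presence, nrow = length(regions))
    .newMarkMatrix(presence, regions, manifest(x), "overlap")
}

#' Windowing representation of a set of peak libraries
#'
#' Divides the genome into fixed-size bins and codes, independently for
#' each library, a 1 for every bin overlapped by at least one of its peaks
#' (a peak straddling a bin boundary lights up both bins).  Only bins
#' overlapped in at least one library are materialised as feature rows;
#' all-zero bins cannot affect Hamming distances.  The default bin size of
#' 200 bp approximates one nucleosome (147 bp of wrapped DNA plus linker),
#' so each bin reflects roughly one histone's modification state.
#'
#' @param x A \linkS4class{PeakLibrarySet}.
#' @param binSize Bin width in bp (default 200).
#' @param chromSizes Optional named vector of chromosome lengths; when
#'   given, peaks extending beyond a declared length raise an error and
#'   the last bin of each chromosome is truncated.
#' @return A \linkS4class{MarkMatrix} (bins by libraries).
#' @examples
#' mm <- windowMatrix(examplePeakLibrarySet(), binSize = 200)
#' dim(mm)
#' @export
windowMatrix <- function(x, binSize = 200, chromSizes = NULL) {
    stopifnot(is(x, "PeakLibrarySet"), binSize >= 1)
    binSize <- as.integer(binSize)
    peakBins <- lapply(x@peaks, function(gr) {
        if (!length(gr))
            return(data.frame(chrom = character(0), bin = integer(0)))
        chrom <- as.character(seqnames(gr))
        if (!is.null(chromSizes)) {
            sz <- chromSizes[chrom]
            bad <- which(is.na(sz) | end(gr) > sz)
            if (length(bad))
                stop(sprintf("peak %s:%d-%d exceeds declared chromosome size",
                             chrom[bad[1L]], start(gr)[bad[1L]] - 1L,
                             end(gr)[bad[1L]]))
        }
        # bins intersected by the half-open peak [start-1, end)
        first <- (start(gr) - 1L) %/% binSize
        last <- (end(gr) - 1L) %/% binSize
        n <- last - first + 1L
        data.frame(chrom = rep(chrom, n),
                   bin = sequence(n, from = first))
    })
    key <- function(df) paste(df$chrom, df$bin)
    univ <- unique(do.call(rbind, peakBins))
    univ <- univ[order(univ$chrom, univ$bin), , drop = FALSE]
    gend <- (univ$bin + 1L) * binSize
    if (!is.null(chromSizes))
        gend <- pmin(gend, unname(chromSizes[univ$chrom]))
    regions <- GRanges(univ$chrom,
                       IRanges(univ$bin * binSize + 1L, gend),
                       binIndex = univ$bin)
    presence <- vapply(peakBins, function(df)
        as.integer(key(univ) %in% key(df)), integer(nrow(univ)))
    if (nrow(univ) == 0L)
        presence <- matrix(integer(0), 0L, length(peakBins))
    if (is.null(dim(presence)))
        presence <- matrix(presence, nrow = nrow(univ))
    .newMarkMatrix(presence, regions, manifest(x), "window", binSize)
}

#' Replicate-averaged profile of a binary representation
#'
#' Collapses the replicate libraries of each cell type into one profile
#' column whose entries are the fraction of replicates showing the mark:
#' with two replicates the value at a feature is 1 when both replicates
#' have a peak, 0 when neither does, and 0.5 when they disagree.
#'
#' @param x A \linkS4class{MarkMatrix}.
#' @param cellTypes Optional ordered subset of cell types; default all, in
#'   first-appearance order.
#' @return A \linkS4class{MarkProfile} (features by cell types).
#' @examples
#' profileMatrix(overlapMatrix(examplePeakLibrarySet()))
#' @export
profileMatrix <- function(x, cellTypes = NULL) {
    stopifnot(is(x, "MarkMatrix"))
    ct <- colData(x)$cell_type
    if (is.null(cellTypes)) cellTypes <- unique(ct)
    miss <- setdiff(cellTypes, ct)
    if (length(miss))
        stop("cell type(s) with no replicate columns: ",
             paste(miss, collapse = ", "))
    a <- assay(x, "presence")
    prof <- vapply(cellTypes, function(cc)
        rowMeans(a[, ct == cc, drop = FALSE]), numeric(nrow(a)))
    if (nrow(a) == 0L)
        prof <- matrix(numeric(0), 0L, length(cellTypes))
    if (is.null(dim(prof))) prof <- matrix(prof, nrow = nrow(a))
    colnames(prof) <- cellTypes
    se <- SummarizedExperiment(
        assays = list(profile = prof),
        rowRanges = rowRanges(x),
        colData = DataFrame(cell_type = cellTypes, row.names = cellTypes))
    mp <- new("MarkProfile", se)
    metadata(mp) <- metadata(x)
    mp
}

#' Mask near-constant feature columns
#'
#' Noise filter for replicate analyses: removes every feature in which at
#' most one library differs from all the others (constant features and
#' features with a single deviating library), keeping exactly the features
#' whose minority state is carried by at least two libraries.  Such
#' near-constant features either carry no signal or reflect single-library
#' noise.  The operation is idempotent.
#'
#' @param x A \linkS4class{MarkMatrix} with at least 3 libraries.
#' @return The subsetted \linkS4class{MarkMatrix}; a warning is issued
#'   when no feature survives.
#' @export
maskNearConstantColumns <- function(x) {
    stopifnot(is(x, "MarkMatrix"))
    if (ncol(x) < 3L)
        stop("masking needs at least 3 libraries")
    ones <- rowSums(assay(x, "presence"))
    minority <- pmin(ones, ncol(x) - ones)
    keep <- minority >= 2
    if (!any(keep))
        warning("all features are near-constant; empty matrix returned")
    x[keep, ]
}

#' Per-cell-type replicate consensus over unambiguous features
#'
#' For the listed cell types, keeps exactly the features in which every
#' listed type's replicates agree (no within-type ambiguity), and returns
#' the agreed 0/1 value per type.  Cell types with a single replicate can
#' never be ambiguous.
#'
#' @param x A \linkS4class{MarkMatrix}.
#' @param cellTypes Ordered character vector of cell types to include.
#' @return A list with elements \code{consensus} (integer 0/1 matrix,
#'   kept features by cell types, feature ids as row names), \code{kept}
#'   (integer indices of the kept feature rows of \code{x}) and
#'   \code{regions} (the kept \code{GRanges}).
#' @examples
#' consensusByCellType(overlapMatrix(examplePeakLibrarySet()),
#'                     c("A", "B"))$consensus
#' @export
consensusByCellType <- function(x, cellTypes) {
    stopifnot(is(x, "MarkMatrix"), length(cellTypes) >= 1L)
    ct <- colData(x)$cell_type
    miss <- setdiff(cellTypes, ct)
    if (length(miss))
        stop("unknown cell type(s): ", paste(miss, collapse = ", "))
    a <- assay(x, "presence")
    keep <- rep(TRUE, nrow(a))
    vals <- matrix(0L, nrow(a), length(cellTypes),
                   dimnames = list(NULL, cellTypes))
    for (j in seq_along(cellTypes)) {
        cols <- which(ct == cellTypes[j])
        rs <- rowSums(a[, cols, drop = FALSE])
        keep <- keep & (rs == 0L | rs == length(cols))
        vals[, j] <- as.integer(rs == length(cols))
    }
    kept <- which(keep)
    consensus <- vals[kept, , drop = FALSE]
    rownames(consensus) <- featureIds(x)[kept]
    list(consensus = consensus, kept = kept,
         regions = rowRanges(x)[kept])
}

#' Serialize a representation matrix as tab-separated text
#'
#' Writes one row per feature: a \code{feature} id column
#' (\code{chrom:start-end}, BED half-open coordinates) followed by one 0/1
#' column per library.  \code{readMarkMatrix} reads the format back; pass
#' the manifest to restore cell-type/replicate/group annotation.
#'
#' @param x A \linkS4class{MarkMatrix}.
#' @param file Output (input) path.
#' @return \code{writeMarkMatrix}: invisibly, \code{file};
#'   \code{readMarkMatrix}: a \linkS4class{MarkMatrix}.
#' @export
writeMarkMatrix <- function(x, file) {
    stopifnot(is(x, "MarkMatrix"))
    tab <- data.frame(feature = featureIds(x), assay(x, "presence"),
                      check.names = FALSE)
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeMarkMatrix
#' @param manifest Optional manifest \code{data.frame} covering the
#'   matrix's library columns.
#' @param representation Representation label to record
#'   (\code{"overlap"} or \code{"window"}).
#' @export
readMarkMatrix <- function(file, manifest = NULL,
                           representation = "overlap") {
    tab <- utils::read.delim(file, check.names = FALSE,
                             colClasses = "character")
    ids <- setdiff(names(tab), "feature")
    parts <- regmatches(tab$feature,
                        regexec("^(.+):(\\d+)-(\\d+)$", tab$feature))
    bad <- which(lengths(parts) != 4L)
    if (length(bad))
        stop("unparseable feature id: ", tab$feature[bad[1L]])
    chrom <- vapply(parts, `[[`, "", 2L)
    s0 <- as.integer(vapply(parts, `[[`, "", 3L))
    e0 <- as.integer(vapply(parts, `[[`, "", 4L))
    regions <- GRanges(chrom, IRanges(s0 + 1L, e0))
    presence <- vapply(ids, function(j) as.integer(tab[[j]]),
                       integer(nrow(tab)))
    if (nrow(tab) == 0L) presence <- matrix(integer(0), 0L, length(ids))
    if (is.null(dim(presence))) presence <- matrix(presence, nrow = nrow(tab))
    colnames(presence) <- ids
    if (is.null(manifest))
        manifest <- data.frame(library_id = ids, cell_type = ids,
                               replicate = 1L, group = ids)
    manifest <- manifest[match(ids, manifest$library_id), ]
    .newMarkMatrix(presence, regions, manifest, representation)
}

#' Export genomic regions as a BED file
#'
#' @param regions A \code{GRanges}.
#' @param file Output path (plain BED, 0-based half-open, sorted).
#' @return Invisibly, \code{file}.
#' @export
exportRegionsBed <- function(regions, file) {
    regions <- sort(granges(regions))
    tab <- data.frame(chrom = as.character(seqnames(regions)),
                      start = start(regions) - 1L, end = end(regions))
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(file)
}
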