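#' Read a peak file into a sorted GRanges
#'
#' Parses ENCODE narrowPeak / broadPeak or plain BED peak lists into a
#' sorted \link[GenomicRanges]{GRanges}.  Input coordinates are BED
#' convention (0-based, half-open \code{[start, end)}); the returned ranges
#' use the 1-based closed \pkg{GenomicRanges} convention.  For narrowPeak
#' and broadPeak the \eqn{-\log_{10}} p-value is taken from column 8 and
#' stored in the \code{negLogP} metadata column; for \code{bed3} it is
#' absent (\code{NA}); dialect \code{"bed"} reads it from a user-chosen
#' column.
#'
#' @param path Path to an existing, uncompressed peak file.
#' @param dialect One of \code{"narrowPeak"}, \code{"broadPeak"},
#'   \code{"bed3"}, \code{"bed"}.
#' @param pValueColumn 1-based column index holding the \eqn{-\log_{10}}
#'   p-value; required for (and only used by) dialect \code{"bed"}.
#' @return A sorted \code{GRanges} with metadata column \code{negLogP}.
#'   An empty file yields an empty \code{GRanges}.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr2\t10\t50", "chr1\t100\t200"), f)
#' readPeakFile(f, "bed3")
#' @export
readPeakFile <- function(path,
                         dialect = c("narrowPeak", "broadPeak", "bed3", "bed"),
                         pValueColumn = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("peak file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    pcol <- switch(dialect,
        narrowPeak = 8L, broadPeak = 8L, bed3 = NA_integer_,
        bed = {
            if (is.null(pValueColumn))
                stop("dialect 'bed' requires pValueColumn")
            as.integer(pValueColumn)
        })
    if (!length(lines)) {
        gr <- GRanges()
        mcols(gr)$negLogP <- numeric(0)
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    minf <- max(3L, pcol, na.rm = TRUE)
    bad <- which(nf < minf)
    if (length(bad))
        stop(sprintf("%s: line %d has %d field(s); %d required for dialect '%s'",
                     path, bad[1L], nf[bad[1L]], minf, dialect))
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad))
        stop(sprintf("%s: line %d: start/end are not integers", path, bad[1L]))
    bad <- which(start0 < 0L)
    if (length(bad))
        stop(sprintf("%s: line %d: negative start coordinate", path, bad[1L]))
    bad <- which(end0 <= start0)
    if (length(bad))
        stop(sprintf("%s: line %d: end (%d) must exceed start (%d)",
                     path, bad[1L], end0[bad[1L]], start0[bad[1L]]))
    negLogP <- rep(NA_real_, length(lines))
    if (!is.na(pcol)) {
        negLogP <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", pcol)))
        bad <- which(is.na(negLogP))
        if (length(bad))
            stop(sprintf("%s: line %d: column %d is not a numeric -log10 p-value",
                         path, bad[1L], pcol))
        if (any(negLogP < 0))
            stop(path, ": negative -log10 p-values are invalid")
    }
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0), negLogP = negLogP)
    sort(sortSeqlevels(gr))
}

#' Keep only peaks at or above a significance threshold
#'
#' Retains exactly the peaks whose \eqn{-\log_{10}} p-value is greater
#' than or equal to \code{threshold} (an inclusive bound; the conventional
#' noise filter keeps peaks with \code{negLogP >= 10}).  Peak order is
#' preserved.  Filtering twice composes to filtering at the larger
#' threshold.
#'
#' @param x A \code{GRanges} with a \code{negLogP} metadata column, or a
#'   \linkS4class{PeakLibrarySet} (filtered library by library).
#' @param threshold Non-negative \eqn{-\log_{10}} p-value cutoff.
#' @return An object of the same class as \code{x}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 50, 90),
#'        c(20, 60, 100)), negLogP = c(9.9, 10, 12.3))
#' filterBySignificance(gr, 10)   # 2 peaks survive
#' @export
setGeneric("filterBySignificance",
    function(x, threshold = 10) standardGeneric("filterBySignificance"))

#' @rdname filterBySignificance
#' @export
setMethod("filterBySignificance", "GRanges", function(x, threshold = 10) {
    stopifnot(threshold >= 0)
    p <- mcols(x)$negLogP
    if (is.null(p) || anyNA(p))
        stop("peaks lack -log10 p-values; read them with a dialect that ",
             "carries a p-value column (narrowPeak, broadPeak or bed)")
    x[p >= threshold]
})

#' @rdname filterBySignificance
#' @export
setMethod("filterBySignificance", "PeakLibrarySet",
    function(x, threshold = 10) {
        x@peaks <- endoapply(x@peaks, filterBySignificance, threshold)
        x
    })

#' Load a library manifest
#'
#' Reads the tab-separated manifest binding each peak file to a library
#' id, cell type, replicate index and group label.  The file must have a
#' header line \code{path library_id cell_type replicate group}.  Relative
#' paths are resolved against the manifest's own directory.
#'
#' @param path Path to the manifest file.
#' @param checkFiles Verify that every referenced peak file exists
#'   (default \code{TRUE}).
#' @return A \code{data.frame} with the five manifest columns,
#'   \code{path} resolved.
#' @export
loadManifest <- function(path, checkFiles = TRUE) {
    if (!file.exists(path)) stop("manifest not found: ", path)
    m <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("path", "library_id", "cell_type", "replicate", "group")
    miss <- setdiff(need, names(m))
    if (length(miss))
        stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
    m <- m[, need]
    m$replicate <- as.integer(m$replicate)
    if (anyNA(m$replicate) || any(m$replicate < 1L))
        stop("manifest replicate column must hold positive integers")
    dup <- m$library_id[duplicated(m$library_id)]
    if (length(dup))
        stop("duplicate library_id in manifest: ",
             paste(unique(dup), collapse = ", "))
    rel <- !grepl("^(/|[A-Za-z]:)", m$path)
    m$path[rel] <- file.path(dirname(path), m$path[rel])
    if (checkFiles) {
        gone <- m$path[!file.exists(m$path)]
        if (length(gone))
            stop("manifest references missing peak file(s): ",
                 paste(gone, collapse = ", "))
    }
    m
}

#' Load all peak libraries listed in a manifest
#'
#' @param manifest A manifest \code{data.frame} (from
#'   \code{\link{loadManifest}}) or the path to a manifest file.
#' @inheritParams readPeakFile
#' @return A \linkS4class{PeakLibrarySet}.
#' @export
loadPeakLibraries <- function(manifest, dialect = "narrowPeak",
                              pValueColumn = NULL) {
    if (is.character(manifest)) manifest <- loadManifest(manifest)
    grl <- GRangesList(lapply(manifest$path, readPeakFile,
                              dialect = dialect,
                              pValueColumn = pValueColumn))
    names(grl) <- manifest$library_id
    PeakLibrarySet(grl, manifest)
}

#' Write peak libraries as narrowPeak files plus a manifest
#'
#' Serializes each library of a \linkS4class{PeakLibrarySet} as an
#' ENCODE-style narrowPeak file (BED 0-based half-open coordinates;
#' \eqn{-\log_{10}} p-value in column 8, \code{-1} when absent) and writes
#' the accompanying tab-separated manifest.
#'
#' @param x A \linkS4class{PeakLibrarySet}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest file path.
#' @export
writePeakLibraries <- function(x, dir) {
    stopifnot(is(x, "PeakLibrarySet"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- manifest(x)
    m$path <- paste0(m$library_id, ".narrowPeak")
    for (i in seq_len(nrow(m))) {
        gr <- x@peaks[[i]]
        p <- mcols(gr)$negLogP
        if (is.null(p)) p <- rep(NA_real_, length(gr))
        tab <- data.frame(
            chrom = as.character(seqnames(gr)),
            start = start(gr) - 1L, end = end(gr),
            name = sprintf("peak_%d", seq_along(gr)),
            score = 0L, strand = ".", signalValue = 0,
            pValue = ifelse(is.na(p), -1, p), qValue = -1, peak = -1L)
        utils::write.table(tab, file.path(dir, m$path[i]), sep = "\t",
                           quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
    }
    mf <- file.path(dir, "manifest.tsv")
    utils::write.table(
        m[, c("path", "library_id", "cell_type", "replicate", "group")],
        mf, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(mf)
}

#' A small built-in example PeakLibrarySet
#'
#' Two cell types with two replicates each on a toy chromosome; used in
#' documentation examples.
#'
#' @return A \linkS4class{PeakLibrarySet} with 4 libraries.
#' @examples
#' examplePeakLibrarySet()
#' @export
examplePeakLibrarySet <- function() {
    mk <- function(s, e) GRanges("chrT", IRanges(s, e),
                                 negLogP = rep(15, length(s)))
    grl <- GRangesList(
        A_1 = mk(c(101, 501), c(300, 700)),
        A_2 = mk(c(121, 481), c(320, 690)),
        B_1 = mk(c(101, 901), c(300, 1100)),
        B_2 = mk(c(81, 921), c(280, 1080)))
    m <- data.frame(
        library_id = names(grl),
        cell_type = rep(c("A", "B"), each = 2),
        replicate = rep(1:2, 2),
        group = rep(c("G1", "G2"), each = 2))
    PeakLibrarySet(grl, m)
}
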