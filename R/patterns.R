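#' Select group-specific marker regions
#'
#' Finds the features (regions) whose 0/1 coding separates a set of
#' libraries (e.g. all embryonic stem cell replicates) from the rest of
#' the matrix, allowing a bounded number of deviating libraries on each
#' side.  The positive set holds features that are 1 in at least
#' \code{|group| - maxErrors} group libraries and 1 in at most
#' \code{maxErrors} outside libraries; the negative set is the mirror
#' image (marked outside the group, absent within).  With
#' \code{maxErrors = 0} this reduces to an exact all-1/all-0 split; the
#' two sets are disjoint whenever \code{maxErrors} is below half of both
#' side sizes.
#'
#' @param x A \linkS4class{MarkMatrix}.
#' @param groupIds Character vector of library ids forming the group; must
#'   be a non-empty strict subset of the matrix libraries.
#' @param maxErrors Maximum deviating libraries allowed on each side
#'   (default 1).
#' @return A list with \code{GRanges} elements \code{positive} and
#'   \code{negative} (sorted, disjoint regions).
#' @examples
#' mm <- overlapMatrix(examplePeakLibrarySet())
#' selectGroupSpecificRegions(mm, c("A_1", "A_2"), maxErrors = 0)
#' @export
selectGroupSpecificRegions <- function(x, groupIds, maxErrors = 1) {
    stopifnot(is(x, "MarkMatrix"), maxErrors >= 0)
    ids <- colnames(x)
    miss <- setdiff(groupIds, ids)
    if (length(miss))
        stop("unknown library id(s): ", paste(miss, collapse = ", "))
    inside <- ids %in% groupIds
    nIn <- sum(inside); nOut <- sum(!inside)
    if (nIn == 0L || nOut == 0L)
        stop("groupIds must be a non-empty strict subset of the libraries")
    if (maxErrors >= nIn || maxErrors >= nOut)
        stop("maxErrors must be smaller than both the group and its ",
             "complement")
    a <- assay(x, "presence")
    onesIn <- rowSums(a[, inside, drop = FALSE])
    onesOut <- rowSums(a[, !inside, drop = FALSE])
    pos <- onesIn >= nIn - maxErrors & onesOut <= maxErrors
    neg <- onesIn <= maxErrors & onesOut >= nOut - maxErrors
    list(positive = sort(granges(rowRanges(x)[pos])),
         negative = sort(granges(rowRanges(x)[neg])))
}

#' Presence/absence pattern counts along a differentiation path
#'
#' For an ordered sequence of cell types (a differentiation path, e.g.
#' stem-cell culture days D0, D2, D5, D9, D14), takes the per-type
#' replicate consensus over the unambiguous features
#' (\code{\link{consensusByCellType}}), forms for each kept feature the
#' 0/1 pattern string in path order, and counts each pattern.  The
#' all-zero pattern is excluded, so on an overlap-representation matrix
#' restricted to the path the counts sum to the number of unambiguous,
#' non-all-zero features.
#'
#' @param x A \linkS4class{MarkMatrix}.
#' @param path Ordered character vector of cell types.
#' @return A \code{data.frame} with columns \code{pattern} and
#'   \code{count}, sorted by decreasing count then pattern; the path is
#'   attached as attribute \code{"path"}.
#' @examples
#' pathPatternCounts(overlapMatrix(examplePeakLibrarySet()), c("A", "B"))
#' @export
pathPatternCounts <- function(x, path) {
    cons <- consensusByCellType(x, path)$consensus
    pat <- apply(cons, 1L, paste0, collapse = "")
    if (length(pat) == 0L) pat <- character(0)
    pat <- pat[pat != strrep("0", length(path))]
    tab <- table(pat)
    out <- data.frame(pattern = names(tab),
                      count = as.integer(tab))
    out <- out[order(-out$count, out$pattern), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "path") <- path
    out
}

#' Regions whose consensus matches a given path pattern
#'
#' Returns the features whose per-type replicate consensus along the path
#' equals the given 0/1 pattern string, for downstream use (e.g. BED
#' export as input to an enrichment tool).
#'
#' @inheritParams pathPatternCounts
#' @param pattern 0/1 string of the same length as \code{path}.
#' @param bedFile Optional path; when given the regions are also written
#'   as a sorted BED file.
#' @return A sorted \code{GRanges} (empty when no feature matches).
#' @examples
#' mm <- overlapMatrix(examplePeakLibrarySet())
#' regionsMatchingPattern(mm, c("A", "B"), "10")
#' @export
regionsMatchingPattern <- function(x, path, pattern, bedFile = NULL) {
    if (!is.character(pattern) || length(pattern) != 1L ||
        grepl("[^01]", pattern))
        stop("pattern must be a string over {0, 1}")
    if (nchar(pattern) != length(path))
        stop("pattern length (", nchar(pattern),
             ") must equal path length (", length(path), ")")
    cons <- consensusByCellType(x, path)
    pat <- apply(cons$consensus, 1L, paste0, collapse = "")
    hit <- sort(granges(cons$regions[pat == pattern]))
    if (!is.null(bedFile)) exportRegionsBed(hit, bedFile)
    hit
}
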