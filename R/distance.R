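.checkDistInput <- function(m) {
    if (nrow(m) < 2L)
        stop("at least 2 libraries are required for a distance matrix")
}

.asLibraryMatrix <- function(x, assayName, klass) {
    if (is(x, klass)) return(t(assay(x)))
    if (is.matrix(x)) return(x)
    stop("x must be a ", klass, " or a plain matrix with libraries in rows")
}

#' Pairwise Hamming distances between libraries
#'
#' The distance between two libraries is the number of features at which
#' their 0/1 codes differ.  Distances are raw counts (not normalised per
#' feature), so values depend on the number of features; set
#' \code{normalize = TRUE} to divide by the feature count for
#' cross-dataset comparison.
#'
#' @param x A \linkS4class{MarkMatrix}, or a plain 0/1 matrix with one row
#'   per library.
#' @param normalize Divide by the number of features (default
#'   \code{FALSE}).
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   library id.
#' @examples
#' hammingDistance(rbind(a = c(0, 1, 1, 0), b = c(0, 1, 0, 1)))
#' @export
hammingDistance <- function(x, normalize = FALSE) {
    m <- .asLibraryMatrix(x, "presence", "MarkMatrix")
    .checkDistInput(m)
    if (length(m) && !all(m %in% c(0, 1)))
        stop("Hamming distance requires a binary 0/1 matrix")
    storage.mode(m) <- "double"
    d <- m %*% (1 - t(m))
    d <- d + t(d)
    dimnames(d) <- list(rownames(m), rownames(m))
    if (normalize && ncol(m) > 0L) d <- d / ncol(m)
    d
}

#' Pairwise Manhattan distances between profile columns
#'
#' The distance between two cell-type profiles is the sum over features of
#' the absolute difference of their profile values; on 0/1-valued profiles
#' this reduces to the Hamming distance.
#'
#' @param x A \linkS4class{MarkProfile}, or a plain matrix in [0,1] with
#'   one row per cell type.
#' @param normalize Divide by the number of features (default
#'   \code{FALSE}).
#' @return A symmetric numeric matrix with zero diagonal.
#' @examples
#' manhattanDistance(rbind(a = c(1, 0.5, 0), b = c(0, 0.5, 1)))
#' @export
manhattanDistance <- function(x, normalize = FALSE) {
    m <- .asLibraryMatrix(x, "profile", "MarkProfile")
    .checkDistInput(m)
    d <- as.matrix(stats::dist(m, method = "manhattan"))
    dimnames(d) <- list(rownames(m), rownames(m))
    if (normalize && ncol(m) > 0L) d <- d / ncol(m)
    d
}

#' Write / read a square labelled distance matrix
#'
#' Tab-separated square matrix with a leading label column and a header
#' row of labels.
#'
#' @param d Symmetric numeric matrix with dimnames.
#' @param file Output (input) path.
#' @return \code{writeDistanceMatrix}: invisibly, \code{file};
#'   \code{readDistanceMatrix}: a labelled symmetric matrix.
#' @export
writeDistanceMatrix <- function(d, file) {
    tab <- data.frame(label = rownames(d), d, check.names = FALSE)
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(file) {
    tab <- utils::read.delim(file, check.names = FALSE)
    d <- as.matrix(tab[, -1, drop = FALSE])
    rownames(d) <- tab[[1L]]
    storage.mode(d) <- "double"
    d
}
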