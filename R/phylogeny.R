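#' Neighbor-Joining tree from a distance matrix
#'
#' Infers an unrooted tree from a symmetric distance matrix by the
#' Saitou-Nei Neighbor-Joining agglomeration (via \code{\link[ape]{nj}}).
#' NJ is consistent: on an additive (tree-metric) matrix it reconstructs
#' the generating topology and branch lengths exactly.  Any negative
#' branch lengths produced on noisy input are clamped to zero; the number
#' of clamped edges is recorded in the \code{"clampCount"} attribute and
#' all downstream statistics (\code{\link{srRatio}},
#' \code{\link{percentDeviation}}) are computed on the clamped lengths.
#'
#' @param D Symmetric numeric matrix with zero diagonal and row/column
#'   labels (or a \code{dist}).
#' @return An unrooted \code{phylo} whose tips carry the matrix labels,
#'   with attribute \code{clampCount}.
#' @examples
#' D <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighborJoining(D)
#' @export
neighborJoining <- function(D) {
    if (inherits(D, "dist")) D <- as.matrix(D)
    if (!is.matrix(D) || nrow(D) != ncol(D))
        stop("D must be a square distance matrix")
    if (nrow(D) < 3L)
        stop("Neighbor-Joining needs at least 3 taxa")
    if (!isSymmetric(unname(D), tol = 1e-8))
        stop("distance matrix must be symmetric")
    if (any(abs(diag(D)) > 1e-8))
        stop("distance matrix must have a zero diagonal")
    if (any(D < 0))
        stop("distances must be non-negative")
    if (is.null(rownames(D)))
        rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
    tr <- ape::nj(D)
    neg <- tr$edge.length < 0
    tr$edge.length[neg] <- 0
    attr(tr, "clampCount") <- sum(neg)
    tr
}

#' Star-shape ratio (SR) of a tree
#'
#' The sum of the lengths of all leaf-incident edges divided by the total
#' edge length of the tree.  An SR close to 1 means nearly all of the
#' tree's length sits on pendant edges - the tree is effectively
#' star-shaped and carries little hierarchical signal; smaller values
#' indicate informative internal structure.  A "leaf edge" is any edge
#' incident to a degree-1 node of the unrooted tree.  SR is invariant
#' under uniform rescaling of all edge lengths.
#'
#' @param tree A \code{phylo} with edge lengths.
#' @return SR in [0, 1].
#' @examples
#' srRatio(ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);"))  # 4/5
#' @export
srRatio <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    if (is.null(tree$edge.length))
        stop("tree has no edge lengths")
    total <- sum(tree$edge.length)
    if (total <= 0)
        stop("SR is undefined on a tree of total edge length zero")
    deg <- tabulate(tree$edge, nbins = max(tree$edge))
    leafEnd <- deg[tree$edge[, 1]] == 1L | deg[tree$edge[, 2]] == 1L
    sum(tree$edge.length[leafEnd]) / total
}

#' Percent deviation (PD) of tree distances from matrix distances
#'
#' Measures how well an inferred tree represents its input distance
#' matrix: for every unordered leaf pair with positive matrix distance,
#' the relative absolute deviation of the tree path distance from the
#' matrix distance is computed, and PD is 100 times the mean of these
#' deviations.  On an additive matrix and its own NJ tree PD is 0; a
#' large PD indicates the data do not fit any tree well.  Pairs with zero
#' matrix distance (identical libraries) are excluded from the mean.
#'
#' @param tree A \code{phylo} whose tip labels equal the matrix labels.
#' @param D Symmetric distance matrix with labels.
#' @return PD as a percentage (non-negative).
#' @export
percentDeviation <- function(tree, D) {
    stopifnot(inherits(tree, "phylo"), is.matrix(D))
    labs <- tree$tip.label
    if (!setequal(labs, rownames(D)) || length(labs) != nrow(D))
        stop("tree tip labels and distance-matrix labels differ")
    M <- D[labs, labs]
    TD <- stats::cophenetic(tree)[labs, labs]
    iu <- upper.tri(M)
    use <- iu & M > 0
    if (!any(use))
        stop("no leaf pair has positive matrix distance")
    100 * mean(abs(TD[use] - M[use]) / M[use])
}

.tipTypes <- function(tree, manifest, by) {
    if (!by %in% names(manifest))
        stop("manifest has no column '", by, "'")
    map <- stats::setNames(as.character(manifest[[by]]),
                           manifest$library_id)
    miss <- setdiff(tree$tip.label, names(map))
    if (length(miss))
        stop("tree tip(s) absent from manifest: ",
             paste(miss, collapse = ", "))
    unname(map[tree$tip.label])
}

#' Collapse replicate clades to single cell-type leaves
#'
#' Replicates of one cell type are expected to form a cherry (or a larger
#' pure clade) in the inferred tree; the within-clade branch lengths then
#' measure replicate noise, not differentiation.  This transformation
#' removes that noise: every maximal subtree whose leaves all belong to
#' one cell type is replaced by its attachment node, relabelled with the
#' cell type, keeping the attachment edge length; leaves whose type has a
#' single replicate are only relabelled.  When a type's replicates are
#' not monophyletic each maximal pure subtree is collapsed separately and
#' a warning reports the duplicated leaf labels.
#'
#' @param tree A \code{phylo} whose tips are library ids.
#' @param manifest Manifest \code{data.frame} mapping library ids to cell
#'   types (and groups).
#' @param by Manifest column defining the collapsing classes
#'   (\code{"cell_type"}, or \code{"group"} to collapse e.g. an entire
#'   stem-cell clade to one leaf).
#' @return A \code{phylo} with one leaf per surviving class instance.
#' @examples
#' tr <- ape::read.tree(text = "((a1:5,a2:5):1,(b1:4,b2:6):1,c:3);")
#' m <- data.frame(library_id = c("a1","a2","b1","b2","c"),
#'                 cell_type = c("A","A","B","B","C"),
#'                 replicate = c(1,2,1,2,1), group = "G")
#' ape::write.tree(collapseReplicateClades(tr, m))  # (B:1,C:3,A:1);
#' @export
collapseReplicateClades <- function(tree, manifest, by = "cell_type") {
    stopifnot(inherits(tree, "phylo"))
    manifest <- manifest[, c("library_id", by)]
    types <- .tipTypes(tree, manifest, by)
    for (cls in unique(types)) {
        repeat {
            types <- .tipTypes(tree, manifest, by)
            ntip <- length(tree$tip.label)
            if (sum(types == cls) < 2L || ntip < 3L) break
            if (all(types == cls)) {
                warning("all leaves belong to class '", cls,
                        "'; nothing to attach a collapsed clade to")
                break
            }
            # a pure component can span the stored basal node; rooting at
            # a leaf outside the class makes every pure component of the
            # unrooted tree a proper descendant clade
            out <- tree$tip.label[which(types != cls)[1L]]
            tree <- ape::root(tree, outgroup = out, resolve.root = TRUE)
            types <- .tipTypes(tree, manifest, by)
            ntip <- length(tree$tip.label)
            nodes <- ntip + seq_len(tree$Nnode)
            desc <- phangorn::Descendants(tree, nodes, type = "tips")
            pure <- vapply(desc, function(tt)
                length(tt) >= 2L && all(types[tt] == cls), logical(1))
            if (!any(pure)) break
            # the largest pure clade is necessarily maximal
            target <- nodes[pure][which.max(lengths(desc[pure]))]
            tt <- desc[[target - ntip]]
            attachLen <- tree$edge.length[tree$edge[, 2] == target]
            keep <- tree$tip.label[tt[1L]]
            tree <- ape::drop.tip(tree, tree$tip.label[tt[-1L]])
            ki <- which(tree$tip.label == keep)
            tree$edge.length[tree$edge[, 2] == ki] <- attachLen
            tree$tip.label[ki] <- cls
            manifest <- rbind(manifest,
                              stats::setNames(data.frame(cls, cls),
                                              c("library_id", by)))
            manifest <- manifest[!duplicated(manifest$library_id), ]
        }
    }
    if (length(tree$tip.label) >= 3L) tree <- ape::unroot(tree)
    types <- .tipTypes(tree, manifest, by)
    tree$tip.label <- types
    dup <- unique(types[duplicated(types)])
    if (length(dup))
        warning("non-monophyletic replicate set(s) collapsed per pure ",
                "subtree: ", paste(dup, collapse = ", "))
    tree
}

#' Largest group-pure subtrees per group (clustering quality)
#'
#' For each group label, considers every subtree obtainable by cutting a
#' single edge of the unrooted tree whose leaves all belong to that group,
#' keeps the maximal ones (not contained in a larger pure subtree), and
#' reports the leaf counts of the two largest.  A perfectly clustered
#' group of n leaves scores (n, 0); a group split across the tree scores
#' e.g. (6, 1).
#'
#' @param tree A \code{phylo} whose tips are library ids (or any labels
#'   present in the manifest).
#' @param manifest Manifest \code{data.frame}.
#' @param by Manifest column holding the group label (default
#'   \code{"group"}).
#' @return A \code{data.frame} with columns \code{group}, \code{n},
#'   \code{largest}, \code{second}, in first-appearance order of the
#'   manifest.
#' @export
groupPurityStats <- function(tree, manifest, by = "group") {
    stopifnot(inherits(tree, "phylo"))
    types <- .tipTypes(tree, manifest, by)
    ntip <- length(tree$tip.label)
    allTips <- seq_len(ntip)
    desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode),
                                  type = "tips")
    sides <- list()
    for (e in seq_len(nrow(tree$edge))) {
        s <- desc[[tree$edge[e, 2]]]
        sides[[length(sides) + 1L]] <- sort(s)
        sides[[length(sides) + 1L]] <- setdiff(allTips, s)
    }
    sides <- unique(sides)
    grps <- unique(as.character(manifest[[by]]))
    grps <- grps[grps %in% types]
    out <- lapply(grps, function(g) {
        cand <- Filter(function(s) length(s) && all(types[s] == g), sides)
        if (length(cand)) {
            maximal <- vapply(seq_along(cand), function(i)
                !any(vapply(seq_along(cand), function(j)
                    i != j && length(cand[[i]]) < length(cand[[j]]) &&
                        all(cand[[i]] %in% cand[[j]]), logical(1))),
                logical(1))
            sz <- sort(lengths(cand[maximal]), decreasing = TRUE)
        } else sz <- integer(0)
        data.frame(group = g, n = sum(types == g),
                   largest = if (length(sz)) sz[1L] else 0L,
                   second = if (length(sz) > 1L) sz[2L] else 0L)
    })
    do.call(rbind, out)
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees; 0 means identical topologies.
#'
#' @param t1,t2 \code{phylo} objects over the same leaf label set.
#' @return A non-negative integer.
#' @export
robinsonFoulds <- function(t1, t2) {
    stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
    if (!setequal(t1$tip.label, t2$tip.label) ||
        length(t1$tip.label) != length(t2$tip.label))
        stop("trees must share an identical leaf label set")
    as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

.needsQuote <- function(lab) grepl("[^A-Za-z0-9_.|/-]", lab)

#' Write / read trees in Newick format
#'
#' Thin wrappers around \pkg{ape}'s Newick machinery that additionally
#' single-quote labels containing spaces or other special characters on
#' output (doubling embedded quotes, per the Newick convention) and strip
#' such quotes on input.  Unrooted trees are written with a trifurcating
#' root node; the round trip preserves topology, labels and branch
#' lengths to printed precision.
#'
#' @param tree A \code{phylo}.
#' @param file Output path, or \code{NULL} to return the Newick string.
#' @return \code{writeTreeNewick}: the Newick string (invisibly when
#'   written to a file); \code{readTreeNewick}: a \code{phylo}.
#' @examples
#' readTreeNewick(text = "(A:1,B:2,(C:3,D:4):1);")
#' @export
writeTreeNewick <- function(tree, file = NULL) {
    stopifnot(inherits(tree, "phylo"))
    q <- which(.needsQuote(tree$tip.label))
    # write.tree sanitises special characters, so quoted labels go
    # through as placeholder tokens substituted back afterwards
    orig <- tree$tip.label[q]
    tokens <- sprintf("xQUOTEDLABELx%dx", seq_along(q))
    tree$tip.label[q] <- tokens
    txt <- ape::write.tree(tree)
    for (i in seq_along(q))
        txt <- sub(tokens[i],
                   sprintf("'%s'", gsub("'", "''", orig[i], fixed = TRUE)),
                   txt, fixed = TRUE)
    if (is.null(file)) return(txt)
    writeLines(txt, file)
    invisible(txt)
}

#' @rdname writeTreeNewick
#' @param text Newick string (alternative to \code{file}).
#' @export
readTreeNewick <- function(file = NULL, text = NULL) {
    tr <- tryCatch(
        if (is.null(text)) ape::read.tree(file)
        else ape::read.tree(text = text),
        error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr) || !inherits(tr, "phylo"))
        stop("malformed Newick input")
    quoted <- grepl("^'.*'$", tr$tip.label)
    tr$tip.label[quoted] <- gsub("''", "'",
        sub("^'(.*)'$", "\\1", tr$tip.label[quoted]), fixed = TRUE)
    tr
}
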