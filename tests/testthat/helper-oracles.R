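# Independent oracles and random-instance generators used across the suite.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# Brute-force interesting regions: build the full interval graph by
# pairwise overlap tests and take its connected components via igraph.
# Deliberately independent of the package's sweep (reduce-based) path.
brute_regions <- function(pls) {
    gr <- if (is(pls, "PeakLibrarySet"))
        unlist(peakRanges(pls), use.names = FALSE)
    else unlist(pls, use.names = FALSE)
    if (!length(gr)) return(sort(GRanges()))
    chroms <- sort(unique(as.character(seqnames(gr))))
    chr <- character(0); mins <- integer(0); maxs <- integer(0)
    for (ch in chroms) {
        g <- gr[as.character(seqnames(gr)) == ch]
        s <- start(g); e <- end(g)
        ov <- outer(s, e, "<=") & outer(e, s, ">=")
        gph <- igraph::make_empty_graph(n = length(g), directed = FALSE)
        gph <- igraph::add_edges(gph, t(which(ov, arr.ind = TRUE)))
        memb <- igraph::components(gph)$membership
        mins <- c(mins, as.integer(tapply(s, memb, min)))
        maxs <- c(maxs, as.integer(tapply(e, memb, max)))
        chr <- c(chr, rep(ch, max(memb)))
    }
    sort(GRanges(factor(chr, levels = chroms), IRanges(mins, maxs)))
}

# Random peak libraries over a couple of chromosomes.
random_pls <- function(seed, maxLibs = 8, maxPeaks = 40,
                       chroms = c("c1", "c2"), span = 5000L) {
    set.seed(seed)
    nl <- sample(2:maxLibs, 1L)
    np <- sample.int(maxPeaks, nl, replace = TRUE)
    tot <- sum(np)
    ch <- sample(chroms, tot, replace = TRUE)
    s <- sample.int(span, tot, replace = TRUE) - 1L
    w <- sample.int(200L, tot, replace = TRUE)
    all <- GRanges(ch, IRanges(s + 1L, s + w), negLogP = runif(tot, 0, 20))
    grl <- S4Vectors::split(all, factor(rep.int(seq_len(nl), np)))
    names(grl) <- sprintf("L%02d", seq_len(nl))
    man <- data.frame(library_id = names(grl),
                      cell_type = names(grl), replicate = 1L,
                      group = rep_len(c("g1", "g2"), nl))
    suppressWarnings(PeakLibrarySet(grl, man))
}

# Bare random GRangesList (no manifest plumbing) for region-oracle checks.
random_grl <- function(seed, maxLibs = 20, maxPeaks = 200,
                       chroms = c("c1", "c2", "c3"), span = 50000L) {
    set.seed(seed)
    nl <- sample(2:maxLibs, 1L)
    np <- sample.int(maxPeaks, nl, replace = TRUE)
    tot <- sum(np)
    all <- GRanges(sample(chroms, tot, replace = TRUE),
                   IRanges(sample.int(span, tot, replace = TRUE),
                           width = sample.int(200L, tot, replace = TRUE)))
    S4Vectors::split(all, factor(rep.int(seq_len(nl), np)))
}

# Canonical non-trivial bipartitions of an unrooted tree, as strings.
tree_splits <- function(tr) {
    tr <- ape::unroot(tr)
    ntip <- length(tr$tip.label)
    labs <- sort(tr$tip.label)
    desc <- phangorn::Descendants(tr, ntip + seq_len(tr$Nnode), "tips")
    keys <- vapply(desc, function(tt) {
        a <- sort(tr$tip.label[tt])
        b <- setdiff(labs, a)
        if (length(a) < 2L || length(b) < 2L) return(NA_character_)
        sort(c(paste(a, collapse = "|"), paste(b, collapse = "|")))[1L]
    }, character(1))
    unique(keys[!is.na(keys)])
}

brute_rf <- function(t1, t2) {
    s1 <- tree_splits(t1); s2 <- tree_splits(t2)
    length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# Random additive (tree-metric) distance matrix plus its generating tree.
random_additive <- function(seed, nmin = 5, nmax = 30) {
    set.seed(seed)
    n <- if (nmin == nmax) nmin else sample(nmin:nmax, 1L)
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) runif(k, 0.1, 5))
    list(tree = tr, D = stats::cophenetic(tr))
}

# MarkMatrix from a plain libraries-by-features 0/1 matrix; features are
# placed as disjoint regions on a toy chromosome.
make_mark_matrix <- function(mat, cell_type = rownames(mat),
                             group = cell_type,
                             replicate = rep(1L, nrow(mat))) {
    regions <- GRanges("cM",
        IRanges((seq_len(ncol(mat)) - 1L) * 1000L + 1L, width = 500L))
    man <- data.frame(library_id = rownames(mat), cell_type = cell_type,
                      replicate = replicate, group = group)
    CellTypeTrees:::.newMarkMatrix(t(unname(mat)), regions, man, "overlap")
}

# Random 0/1 matrix with labelled libraries.
random_binary <- function(seed, nlib, nfeat, p = 0.4) {
    set.seed(seed)
    matrix(rbinom(nlib * nfeat, 1L, p), nlib, nfeat,
           dimnames = list(sprintf("L%02d", seq_len(nlib)), NULL))
}

write_bed_lines <- function(lines) {
    f <- tempfile(fileext = ".bed")
    writeLines(lines, f)
    f
}
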