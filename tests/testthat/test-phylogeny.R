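quartetD <- matrix(c(0, 3, 5, 6,
                     3, 0, 6, 7,
                     5, 6, 0, 7,
                     6, 7, 7, 0), 4, 4,
                   dimnames = list(LETTERS[1:4], LETTERS[1:4]))

test_that("NJ resolves the additive quartet with exact branch lengths", {
    tr <- neighborJoining(quartetD)
    expect_identical(tree_splits(tr), "A|B")  # split AB|CD
    ntip <- 4L
    internal <- tr$edge[, 2] > ntip
    expect_equal(tr$edge.length[internal], 1)
    leafLen <- tr$edge.length[match(seq_len(ntip), tr$edge[, 2])]
    expect_equal(leafLen[match(LETTERS[1:4], tr$tip.label)],
                 c(1, 2, 3, 4))
    expect_equal(attr(tr, "clampCount"), 0L)
})

test_that("NJ three-taxon star has the analytic branch lengths", {
    D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    tr <- neighborJoining(D)
    lens <- tr$edge.length[match(1:3, tr$edge[, 2])]
    names(lens) <- tr$tip.label
    expect_equal(unname(lens[c("a", "b", "c")]), c(1, 2, 4))
    # ultrametric equidistant taxa: all leaf edges equal
    E <- matrix(2, 3, 3, dimnames = dimnames(D)); diag(E) <- 0
    expect_equal(unique(neighborJoining(E)$edge.length), 1)
})

test_that("NJ validates its input", {
    expect_error(neighborJoining(quartetD[1:2, 1:2]), "3 taxa")
    asym <- quartetD; asym[1, 2] <- 99
    expect_error(neighborJoining(asym), "symmetric")
    offdiag <- quartetD; diag(offdiag) <- 1
    expect_error(neighborJoining(offdiag), "diagonal")
})

test_that("NJ is consistent on additive matrices (topology and fit)", {
    for (s in 1:20) {
        inst <- random_additive(5000 + s, 5, 20)
        tr <- neighborJoining(inst$D)
        expect_equal(robinsonFoulds(tr, inst$tree), 0L)
        expect_lt(percentDeviation(tr, inst$D), 1e-7)
    }
})

test_that("SR ratio measures star-likeness and scales invariantly", {
    star <- ape::read.tree(text = "(A:1,B:2,C:3,D:4);")
    expect_equal(srRatio(star), 1)
    quartet <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
    expect_equal(srRatio(quartet), 0.8)
    # long internal edges drive SR toward 0
    skinny <- ape::read.tree(text = "((A:0.01,B:0.01):100,C:0.01,D:0.01);")
    expect_lt(srRatio(skinny), 0.01)
    # invariance under uniform rescaling
    q2 <- quartet; q2$edge.length <- q2$edge.length * 7.3
    expect_equal(srRatio(q2), srRatio(quartet))
    zero <- quartet; zero$edge.length[] <- 0
    expect_error(srRatio(zero), "undefined")
    for (s in 1:10) {
        tr <- random_additive(600 + s, 4, 15)$tree
        expect_gte(srRatio(tr), 0); expect_lte(srRatio(tr), 1)
    }
})

test_that("percent deviation measures tree fit as mean relative error", {
    tr <- neighborJoining(quartetD)
    expect_lt(percentDeviation(tr, quartetD), 1e-9)
    # doubling every edge makes every pair deviate by exactly 100%
    tr2 <- tr; tr2$edge.length <- tr2$edge.length * 2
    expect_equal(percentDeviation(tr2, quartetD), 100)
    # invariant under consistent relabeling
    perm <- c(A = "W", B = "X", C = "Y", D = "Z")
    trP <- tr; trP$tip.label <- unname(perm[trP$tip.label])
    DP <- quartetD; dimnames(DP) <- list(perm, perm)
    expect_equal(percentDeviation(trP, DP), percentDeviation(tr, quartetD))
    expect_error(percentDeviation(tr, DP), "labels")
    # perturbing the matrix grows PD in expectation
    set.seed(42)
    pd <- vapply(c(0.1, 0.5, 1.5), function(eps) {
        mean(vapply(1:20, function(i) {
            E <- matrix(runif(16, 0, eps), 4, 4); E <- E + t(E); diag(E) <- 0
            percentDeviation(tr, quartetD + E)
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(pd) > 0))
})

test_that("replicate clades collapse to their attachment node", {
    tr <- ape::read.tree(text = "((a1:5,a2:5):1,(b1:4,b2:6):1,c:3);")
    m <- data.frame(library_id = c("a1", "a2", "b1", "b2", "c"),
                    cell_type = c("A", "A", "B", "B", "C"),
                    replicate = c(1, 2, 1, 2, 1), group = "G")
    cl <- collapseReplicateClades(tr, m)
    expect_setequal(cl$tip.label, c("A", "B", "C"))
    lens <- cl$edge.length[match(1:3, cl$edge[, 2])]
    names(lens) <- cl$tip.label
    expect_equal(unname(lens[c("A", "B", "C")]), c(1, 1, 3))

    # all-singleton types: pure relabelling, topology unchanged
    m2 <- m; m2$cell_type <- toupper(m2$library_id)
    cl2 <- collapseReplicateClades(tr, m2)
    expect_equal(robinsonFoulds(cl2, {
        t3 <- tr; t3$tip.label <- toupper(t3$tip.label); t3
    }), 0L)

    # a larger pure clade collapses to a single leaf, and distances among
    # untouched leaves are preserved
    big <- ape::read.tree(text =
        "(((h1:1,h2:1):1,(h3:1,(h4:1,h5:1):1):1):2,(x:4,y:5):1,z:6);")
    mb <- data.frame(library_id = c(paste0("h", 1:5), "x", "y", "z"),
                     cell_type = c(rep("hESC", 5), "X", "Y", "Z"),
                     replicate = 1, group = "G")
    clb <- collapseReplicateClades(big, mb)
    expect_setequal(clb$tip.label, c("hESC", "X", "Y", "Z"))
    expect_equal(clb$edge.length[match(which(clb$tip.label == "hESC"),
                                       clb$edge[, 2])], 2)
    d0 <- stats::cophenetic(big)[c("x", "y", "z"), c("x", "y", "z")]
    d1 <- stats::cophenetic(clb)[c("X", "Y", "Z"), c("X", "Y", "Z")]
    expect_equal(unname(d1), unname(d0))

    # replicates forming a cherry across the stored basal node
    tr3 <- ape::read.tree(text = "(a1:2,a2:3,(b1:4,(b2:1,c:5):1):1);")
    expect_warning(cl3 <- collapseReplicateClades(tr3, m),
                   "non-monophyletic")
    expect_equal(sum(cl3$tip.label == "A"), 1L)
    expect_equal(sum(cl3$tip.label == "B"), 2L)
})

test_that("group purity statistics report the two largest pure subtrees", {
    tr <- ape::read.tree(text =
        "(((g1:1,g2:1):1,(g3:1,g4:1):1):1,((g5:1,h1:1):1,(h2:1,g6:1):1):1);")
    m <- data.frame(library_id = c(paste0("g", 1:6), "h1", "h2"),
                    cell_type = c(paste0("g", 1:6), "h1", "h2"),
                    replicate = 1,
                    group = c(rep("G", 6), "H", "H"))[c(1:5, 8, 7, 6), ]
    st <- groupPurityStats(tr, m)
    g <- st[st$group == "G", ]
    expect_equal(c(g$n, g$largest, g$second), c(6, 4, 1))
    h <- st[st$group == "H", ]
    expect_equal(c(h$largest, h$second), c(1, 1))

    # a perfectly clustered group scores (n, 0); singleton groups (1, 0)
    tr2 <- ape::read.tree(text = "(((a1:1,a2:1):1,a3:1):1,(b1:1,b2:1):1,c:1);")
    m2 <- data.frame(library_id = c("a1", "a2", "a3", "b1", "b2", "c"),
                     cell_type = 1:6, replicate = 1,
                     group = c("A", "A", "A", "B", "B", "C"))
    st2 <- groupPurityStats(tr2, m2)
    expect_equal(st2$largest, c(3L, 2L, 1L))
    expect_equal(st2$second, c(0L, 0L, 0L))
})

test_that("Robinson-Foulds agrees with brute-force split comparison", {
    t1 <- ape::read.tree(text = "((A,B),C,D);")
    t2 <- ape::read.tree(text = "((A,C),B,D);")
    expect_equal(robinsonFoulds(t1, t1), 0L)
    expect_equal(robinsonFoulds(t1, t2), 2L)
    cat6 <- ape::read.tree(text = "(((((A,B),C),D),E),F);")
    bal6 <- ape::read.tree(text = "(((A,B),C),((D,E),F));")
    expect_equal(robinsonFoulds(cat6, bal6), brute_rf(cat6, bal6))
    for (s in 1:10) {
        ta <- random_additive(100 + s, 5, 12)$tree
        n <- length(ta$tip.label)
        tb <- random_additive(200 + s, n, n)$tree
        set.seed(s)
        tb$tip.label <- sample(ta$tip.label)
        expect_equal(robinsonFoulds(ta, tb), brute_rf(ta, tb))
    }
    t3 <- ape::read.tree(text = "((A,B),C,E);")
    expect_error(robinsonFoulds(t1, t3), "label set")
})

test_that("Newick round-trip preserves topology, labels and lengths", {
    txt <- "(A:1,B:2,(C:3,D:4):1);"
    tr <- readTreeNewick(text = txt)
    expect_equal(writeTreeNewick(tr), txt)
    # write-parse-write is a fixed point
    tr2 <- neighborJoining(quartetD)
    once <- writeTreeNewick(tr2)
    expect_equal(writeTreeNewick(readTreeNewick(text = once)), once)
    # labels with spaces are quoted and recovered
    trs <- tr; trs$tip.label[1] <- "CD20 (1)"
    out <- writeTreeNewick(trs)
    expect_match(out, "'CD20 (1)'", fixed = TRUE)
    expect_equal(readTreeNewick(text = out)$tip.label[1], "CD20 (1)")
    # file round trip
    f <- tempfile(fileext = ".nwk")
    writeTreeNewick(tr2, f)
    back <- readTreeNewick(f)
    expect_equal(robinsonFoulds(back, tr2), 0L)
    expect_equal(sort(back$edge.length), sort(tr2$edge.length))
    expect_error(readTreeNewick(text = "(A:1,B:2"), "malformed")
})
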