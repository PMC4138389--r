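pls_from <- function(...) {
    grl <- list(...)
    man <- data.frame(library_id = names(grl), cell_type = names(grl),
                      replicate = 1L, group = names(grl))
    suppressWarnings(PeakLibrarySet(GRangesList(grl), man))
}

bed_gr <- function(chrom, s0, e0)
    GRanges(chrom, IRanges(s0 + 1L, e0))

test_that("interesting regions are interval-graph components", {
    # A: [100,200)+[250,300); B: [150,260) chains them into one region
    pls <- pls_from(A = bed_gr("c1", c(100, 250), c(200, 300)),
                    B = bed_gr("c1", 150, 260))
    ir <- interestingRegions(pls)
    expect_length(ir, 1L)
    expect_identical(c(start(ir) - 1L, end(ir)), c(100L, 300L))

    # disjoint peaks stay apart; touching half-open intervals too
    pls <- pls_from(A = bed_gr("c1", c(0, 20), c(10, 30)))
    expect_length(interestingRegions(pls), 2L)
    pls <- pls_from(A = bed_gr("c1", 0, 10), B = bed_gr("c1", 10, 20))
    expect_length(interestingRegions(pls), 2L)

    # no peaks at all
    empty <- pls_from(A = GRanges())
    expect_length(interestingRegions(empty), 0L)
})

test_that("interesting regions match the brute-force interval-graph oracle", {
    for (s in 1:40) {
        pls <- random_pls(seed = 7000 + s)
        expect_identical(granges(interestingRegions(pls)),
                         granges(brute_regions(pls)),
                         info = paste("seed", 7000 + s))
    }
})

test_that("regions are disjoint and cover every input peak", {
    for (s in 1:10) {
        pls <- random_pls(seed = 4200 + s)
        ir <- interestingRegions(pls)
        expect_true(all(countOverlaps(ir, ir) == 1L))
        allp <- unlist(peakRanges(pls), use.names = FALSE)
        hits <- findOverlaps(allp, ir, type = "within")
        expect_equal(length(unique(S4Vectors::queryHits(hits))),
                     length(allp))
    }
})

test_that("windowing codes any-overlap per bin, independently per library", {
    pls <- pls_from(A = bed_gr("c1", 150, 250))
    wm <- windowMatrix(pls, binSize = 200)
    expect_equal(nrow(wm), 2L)     # bins [0,200) and [200,400)
    expect_identical(unname(presenceMatrix(wm)[1, ]), c(1L, 1L))
    expect_identical(rowRanges(wm)$binIndex, c(0L, 1L))

    # a library's coding does not depend on which other libraries exist
    plsAB <- pls_from(A = bed_gr("c1", 150, 250),
                      B = bed_gr("c1", c(700, 1300), c(900, 1350)))
    wmAB <- windowMatrix(plsAB, binSize = 200)
    onA <- featureIds(wmAB)[presenceMatrix(wmAB)["A", ] == 1L]
    expect_identical(onA, featureIds(wm))

    # identical libraries produce identical rows, Hamming 0
    pls2 <- pls_from(A = bed_gr("c1", c(0, 500), c(100, 900)),
                     B = bed_gr("c1", c(0, 500), c(100, 900)))
    wm2 <- windowMatrix(pls2)
    expect_equal(unname(hammingDistance(wm2)["A", "B"]), 0)

    # chromosome sizes are enforced and truncate the last bin
    expect_error(windowMatrix(pls, binSize = 200,
                              chromSizes = c(c1 = 220)), "exceeds")
    wm3 <- windowMatrix(pls, binSize = 200, chromSizes = c(c1 = 260))
    expect_equal(end(rowRanges(wm3))[2], 260L)
})

test_that("overlap matrix codes regions jointly with no all-zero column", {
    pls <- pls_from(A = bed_gr("c1", c(100, 250), c(200, 300)),
                    B = bed_gr("c1", 150, 260),
                    C = bed_gr("c2", 0, 50))
    om <- overlapMatrix(pls)
    pm <- presenceMatrix(om)
    expect_equal(dim(pm), c(3L, 2L))
    expect_identical(unname(pm[, 1]), c(1L, 1L, 0L))  # merged c1 region
    expect_identical(unname(pm[, 2]), c(0L, 0L, 1L))  # C-only region
    expect_true(all(colSums(pm) >= 1L))

    # N identical libraries: all-ones matrix, one column per peak run
    pls2 <- pls_from(A = bed_gr("c1", c(0, 500), c(100, 900)),
                     B = bed_gr("c1", c(0, 500), c(100, 900)),
                     C = bed_gr("c1", c(0, 500), c(100, 900)))
    expect_true(all(presenceMatrix(overlapMatrix(pls2)) == 1L))
    expect_equal(ncol(presenceMatrix(overlapMatrix(pls2))), 2L)
})

test_that("profiles average replicates per cell type", {
    mat <- rbind(A_1 = c(1L, 1L, 0L, 1L), A_2 = c(0L, 1L, 0L, 1L),
                 B_1 = c(1L, 0L, 1L, 0L))
    mm <- make_mark_matrix(mat, cell_type = c("A", "A", "B"),
                           replicate = c(1L, 2L, 1L))
    pr <- profileMatrix(mm)
    expect_equal(unname(assay(pr)[, "A"]), c(0.5, 1, 0, 1))
    # single-replicate type reproduces its row exactly
    expect_equal(unname(assay(pr)[, "B"]), unname(mat["B_1", ]))
    # copies of one row reproduce that row
    mm2 <- make_mark_matrix(rbind(X_1 = c(1L, 0L, 1L),
                                  X_2 = c(1L, 0L, 1L)),
                            cell_type = c("X", "X"),
                            replicate = c(1L, 2L))
    expect_equal(unname(assay(profileMatrix(mm2))[, "X"]), c(1, 0, 1))
    expect_error(profileMatrix(mm, "Z"), "no replicate")
})

test_that("masking removes features where at most one library deviates", {
    mat <- rbind(L1 = c(1L, 1L, 1L, 0L),
                 L2 = c(1L, 0L, 1L, 0L),
                 L3 = c(1L, 1L, 0L, 1L),
                 L4 = c(1L, 1L, 0L, 1L))
    mm <- make_mark_matrix(mat)
    kept <- maskNearConstantColumns(mm)
    # col1 constant, col2 single deviant -> dropped; col3/col4 kept (2 vs 2)
    expect_equal(nrow(kept), 2L)
    expect_identical(unname(presenceMatrix(kept)),
                     unname(mat[, 3:4]))
    # idempotent
    expect_identical(presenceMatrix(maskNearConstantColumns(kept)),
                     presenceMatrix(kept))
    # everything near-constant -> empty with warning
    allc <- make_mark_matrix(rbind(L1 = c(1L, 0L), L2 = c(1L, 0L),
                                   L3 = c(1L, 1L)))
    expect_warning(res <- maskNearConstantColumns(allc), "near-constant")
    expect_equal(nrow(res), 0L)
    expect_error(maskNearConstantColumns(make_mark_matrix(mat[1:2, ])),
                 "3 libraries")
})

test_that("consensus keeps only features without replicate ambiguity", {
    mat <- rbind(A_1 = c(1L, 1L, 0L), A_2 = c(1L, 0L, 0L),
                 B_1 = c(0L, 1L, 1L), B_2 = c(0L, 1L, 1L))
    mm <- make_mark_matrix(mat, cell_type = c("A", "A", "B", "B"),
                           replicate = c(1L, 2L, 1L, 2L))
    cons <- consensusByCellType(mm, c("A", "B"))
    expect_identical(cons$kept, c(1L, 3L))   # feature 2 is A-ambiguous
    expect_identical(unname(cons$consensus),
                     rbind(c(1L, 0L), c(0L, 1L)))
    # single-replicate types never cause ambiguity
    cons2 <- consensusByCellType(mm[, "A_1"], "A")
    expect_length(cons2$kept, 3L)
    expect_error(consensusByCellType(mm, "Z"), "unknown cell type")
})

test_that("matrix and region serialization round-trips", {
    pls <- examplePeakLibrarySet()
    mm <- overlapMatrix(pls)
    f <- tempfile(fileext = ".tsv")
    writeMarkMatrix(mm, f)
    back <- readMarkMatrix(f, manifest = manifest(pls))
    expect_identical(presenceMatrix(back), presenceMatrix(mm))
    expect_identical(granges(rowRanges(back)), granges(rowRanges(mm)))
    expect_identical(colData(back)$cell_type, colData(mm)$cell_type)

    bed <- tempfile(fileext = ".bed")
    exportRegionsBed(rowRanges(mm), bed)
    lines <- read.delim(bed, header = FALSE)
    expect_equal(nrow(lines), nrow(mm))
    expect_equal(lines$V2, start(rowRanges(mm)) - 1L)
})
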