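#' Construct a simulation configuration
#'
#' See \linkS4class{SimulationConfig} for the meaning of every parameter.
#' The defaults describe the package's reference simulation: 12 cell
#' types x 2 replicates, 5000 regions of 1 kb separated by 500 bp gaps,
#' per-edge flip probabilities uniform in [0.02, 0.1], 1\% replicate
#' noise, 100 bp boundary jitter, and 90\% of peaks drawn above the
#' conventional significance threshold.
#'
#' @param nCellTypes,replicatesPerType,nRegions,rootPresenceProb,edgeFlipMin,edgeFlipMax,replicateFlipProb,gainProb,lossProb,regionLengthBp,gapBp,boundaryJitterBp,significantFraction,seed
#'   See \linkS4class{SimulationConfig}.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig(nCellTypes = 4, nRegions = 100, seed = 7)
#' @export
simulationConfig <- function(nCellTypes = 12, replicatesPerType = 2,
                             nRegions = 5000, rootPresenceProb = 0.5,
                             edgeFlipMin = 0.02, edgeFlipMax = 0.1,
                             replicateFlipProb = 0.01,
                             gainProb = NA_real_, lossProb = NA_real_,
                             regionLengthBp = 1000, gapBp = 500,
                             boundaryJitterBp = 100,
                             significantFraction = 0.9, seed = 1) {
    new("SimulationConfig",
        nCellTypes = as.integer(nCellTypes),
        replicatesPerType = as.integer(replicatesPerType),
        nRegions = as.integer(nRegions),
        rootPresenceProb = as.numeric(rootPresenceProb),
        edgeFlipMin = as.numeric(edgeFlipMin),
        edgeFlipMax = as.numeric(edgeFlipMax),
        replicateFlipProb = as.numeric(replicateFlipProb),
        gainProb = as.numeric(gainProb), lossProb = as.numeric(lossProb),
        regionLengthBp = as.integer(regionLengthBp),
        gapBp = as.integer(gapBp),
        boundaryJitterBp = as.integer(boundaryJitterBp),
        significantFraction = as.numeric(significantFraction),
        seed = as.integer(seed))
}

#' Simulate gain/loss of a mark along a random cell-type tree
#'
#' Draws a random rooted bifurcating tree over the configured cell types
#' (uniform over labelled topologies), assigns each region an independent
#' Bernoulli root state, and evolves the 0/1 states down every edge by
#' independent per-region flips.  Under the default symmetric model each
#' edge's flip probability is drawn uniformly in
#' [\code{edgeFlipMin}, \code{edgeFlipMax}]; when \code{gainProb} /
#' \code{lossProb} are set, 0 to 1 and 1 to 0 transitions use those rates
#' instead (loss of a mark being the more frequent event during
#' development motivates the asymmetric option).  Fully reproducible from
#' the configuration seed.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GainLossTruth}.
#' @examples
#' truth <- simulateGainLoss(simulationConfig(nCellTypes = 4,
#'                                            nRegions = 50, seed = 3))
#' truth
#' @export
simulateGainLoss <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    n <- config@nCellTypes
    R <- config@nRegions
    tree <- ape::rtopology(n, rooted = TRUE,
                           tip.label = sprintf("CT%02d", seq_len(n)))
    tree <- stats::reorder(tree, "postorder")
    nEdge <- nrow(tree$edge)
    asym <- !is.na(config@gainProb)
    edgeP <- if (asym) rep(config@gainProb, nEdge)
             else stats::runif(nEdge, config@edgeFlipMin, config@edgeFlipMax)
    tree$edge.length <- edgeP
    states <- matrix(0L, n + tree$Nnode, R)
    root <- n + 1L
    states[root, ] <- stats::rbinom(R, 1L, config@rootPresenceProb)
    # parents precede children when edges are walked in reverse postorder
    for (e in rev(seq_len(nEdge))) {
        p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
        parent <- states[p, ]
        if (asym) {
            u <- stats::runif(R)
            flip <- ifelse(parent == 1L, u < config@lossProb,
                           u < config@gainProb)
        } else flip <- stats::rbinom(R, 1L, edgeP[e]) == 1L
        states[ch, ] <- as.integer(xor(parent == 1L, flip))
    }
    step <- config@regionLengthBp + config@gapBp
    regions <- GRanges("chrS",
        IRanges(start = (seq_len(R) - 1L) * step + 1L,
                width = config@regionLengthBp))
    new("GainLossTruth", tree = tree, nodeStates = states,
        regions = regions, edgeFlipProb = edgeP)
}

#' Emit peak libraries from a simulated truth
#'
#' For every leaf cell type and replicate, copies the leaf's state
#' vector, flips each entry independently with \code{replicateFlipProb},
#' and converts every remaining 1 into a peak on the synthetic
#' chromosome: region r occupies \code{[r*(L+G), r*(L+G)+L)} (BED
#' coordinates) and each emitted endpoint is jittered by at most
#' \code{boundaryJitterBp}.  Because the jitter is below half the
#' inter-region gap, jittered peaks from adjacent truth regions can never
#' merge.  Each peak receives a \eqn{-\log_{10}} p-value: with
#' probability \code{significantFraction} from \code{10 + Exponential}
#' (rate 0.2, above the conventional threshold of 10), otherwise uniform
#' on [0, 10), so significance filtering is exercisable.  Reproducible
#' from the configuration seed (offset so that truth and emission draws
#' do not interleave).
#'
#' @param truth A \linkS4class{GainLossTruth} from
#'   \code{\link{simulateGainLoss}}.
#' @param config The same \linkS4class{SimulationConfig}.
#' @return A \linkS4class{PeakLibrarySet} with libraries
#'   \code{<cellType>_r<replicate>}; the manifest's \code{group} equals
#'   the cell type.
#' @export
emitPeakLibraries <- function(truth, config) {
    stopifnot(is(truth, "GainLossTruth"), is(config, "SimulationConfig"))
    if (config@regionLengthBp <= 2L * config@boundaryJitterBp)
        stop("regionLengthBp must exceed twice boundaryJitterBp")
    set.seed(config@seed + 1L)
    tips <- truth@tree$tip.label
    R <- ncol(truth@nodeStates)
    s0 <- start(truth@regions) - 1L
    e0 <- end(truth@regions)
    j <- config@boundaryJitterBp
    grl <- list(); man <- list()
    for (i in seq_along(tips)) {
        for (r in seq_len(config@replicatesPerType)) {
            s <- truth@nodeStates[i, ]
            if (config@replicateFlipProb > 0) {
                flip <- stats::rbinom(R, 1L, config@replicateFlipProb)
                s <- as.integer(xor(s == 1L, flip == 1L))
            }
            idx <- which(s == 1L)
            n1 <- length(idx)
            js <- if (j > 0L) sample(seq(-j, j), n1, replace = TRUE)
                  else integer(n1)
            je <- if (j > 0L) sample(seq(-j, j), n1, replace = TRUE)
                  else integer(n1)
            ps <- pmax(s0[idx] + js, 0L)
            pe <- e0[idx] + je
            sig <- stats::runif(n1) < config@significantFraction
            nlp <- ifelse(sig, 10 + stats::rexp(n1, 0.2),
                          stats::runif(n1, 0, 10))
            id <- sprintf("%s_r%d", tips[i], r)
            grl[[id]] <- sort(GRanges("chrS", IRanges(ps + 1L, pe),
                                      negLogP = nlp))
            man[[id]] <- data.frame(library_id = id, cell_type = tips[i],
                                    replicate = r, group = tips[i])
        }
    }
    PeakLibrarySet(GRangesList(grl), do.call(rbind, man))
}

#' End-to-end recovery harness on simulated data
#'
#' Runs the full pipeline on one simulated dataset: simulate gain/loss
#' truth, emit peak libraries, build the overlap representation, compute
#' Hamming distances, infer the NJ tree, collapse replicate clades, and
#' compare the collapsed tree against the true tree by Robinson-Foulds
#' distance.  Deterministic given the configuration seed.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return A list: \code{rf} (Robinson-Foulds distance to the truth,
#'   \code{NA} when replicate sets were not monophyletic so leaf sets
#'   differ), \code{sr} and \code{pd} (statistics of the replicate-level
#'   tree), \code{clampCount} (negative NJ branch lengths clamped),
#'   \code{tree} (replicate-level NJ tree), \code{collapsedTree}, and
#'   \code{truth}.
#' @examples
#' recoveryHarness(simulationConfig(nCellTypes = 5, nRegions = 300,
#'                                  seed = 11))$rf
#' @export
recoveryHarness <- function(config) {
    truth <- simulateGainLoss(config)
    pls <- emitPeakLibraries(truth, config)
    mm <- overlapMatrix(pls)
    D <- hammingDistance(mm)
    tree <- neighborJoining(D)
    sr <- srRatio(tree)
    pd <- percentDeviation(tree, D)
    collapsed <- withCallingHandlers(
        collapseReplicateClades(tree, manifest(pls)),
        warning = function(w) invokeRestart("muffleWarning"))
    rf <- tryCatch(robinsonFoulds(collapsed, truth@tree),
                   error = function(e) NA_integer_)
    list(rf = rf, sr = sr, pd = pd,
         clampCount = attr(tree, "clampCount"),
         tree = tree, collapsedTree = collapsed, truth = truth)
}
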