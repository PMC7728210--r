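#' Default M_cut search grid
#'
#' The search resolution used on real cohorts: steps of 2000 ranks, here
#' spanning 2000–100000.
#'
#' @param from,to,by Grid limits and increment.
#' @return Increasing integer vector.
#' @export
mCutGrid <- function(from = 2000, to = 100000, by = 2000) {
    seq(from, to, by = by)
}

#' Default p_G search grid
#'
#' Spans \eqn{1.5 \le -\log_{10} p_G \le 4}, the region the method's
#' exploratory \eqn{M_{cut} = \infty} scan identifies as worth searching.
#'
#' @param negLog10 Vector of \eqn{-\log_{10} p_G} values.
#' @return Numeric vector of \eqn{p_G} values.
#' @export
pGGrid <- function(negLog10 = seq(1.5, 4, by = 0.5)) {
    10^(-negLog10)
}

## Internal: one pipeline pass at fixed (mCut, method) from ranked sets.
.penaltyAt <- function(rankedSets, labels, mCut, method) {
    tracks <- lapply(rankedSets, binarize, mCut = mCut)
    d <- distanceMatrix(tracks, metric = "hamming")
    dendro <- agglomerate(d, method = method)
    penaltyReport(dendro, labels)
}

#' Grid search for the optimal (M_cut, p_G)
#'
#' For every grid point, runs the full pipeline — truncate each sample's
#' ranked peaks at \eqn{M_{cut}}, binarize, assemble the Hamming distance
#' matrix, agglomerate, score the labeled dendrogram — and records the
#' global and per-type penalties. The optimum \eqn{(M_{cut}^*, p_G^*)}
#' is the grid minimum of \eqn{\lambda}; when several contiguous
#' \eqn{M_{cut}} values tie at the minimum, the plateau midpoint is
#' selected (see [plateauMidpoint()]). Among tying \eqn{p_G} values the
#' one with the longest minimizing plateau wins (first on further ties).
#'
#' @param peaksByPG Either a named list mapping sample id to
#'   [RankedPeakSet-class] (a single \eqn{p_G}), or a list of such lists
#'   whose names are the \eqn{p_G} values (peak calls are \eqn{p_G}-
#'   specific, so one ranked set per sample per \eqn{p_G}).
#' @param labels Named character vector of sample types.
#' @param mCuts Increasing integer vector of \eqn{M_{cut}} values
#'   (default [mCutGrid()]).
#' @param method Linkage method (default \code{"ward"}).
#' @return A [GridResult-class].
#' @export
gridSearch <- function(peaksByPG, labels, mCuts = mCutGrid(),
                       method = "ward") {
    if (!length(mCuts)) stop("mCuts must be a non-empty grid")
    if (is.unsorted(mCuts, strictly = TRUE))
        stop("mCuts must be strictly increasing")
    ## normalize to list(pG -> list(sample -> RankedPeakSet))
    if (length(peaksByPG) && is(peaksByPG[[1]], "RankedPeakSet")) {
        pGs <- pGThreshold(peaksByPG[[1]])
        peaksByPG <- stats::setNames(list(peaksByPG), format(pGs))
    } else {
        pGs <- vapply(peaksByPG,
                      function(l) pGThreshold(l[[1]]), numeric(1))
    }
    tabs <- list(); sums <- list()
    for (gi in seq_along(peaksByPG)) {
        rankedSets <- peaksByPG[[gi]]
        for (m in mCuts) {
            report <- .penaltyAt(rankedSets, labels, m, method)
            report$pG <- pGs[gi]; report$mCut <- m
            tabs[[length(tabs) + 1L]] <- report
            sums[[length(sums) + 1L]] <-
                data.frame(pG = pGs[gi], mCut = m,
                           lambda = sum(report$lambdaNu))
        }
    }
    tab <- do.call(rbind, tabs)
    summ <- do.call(rbind, sums)
    lamMin <- min(summ$lambda)
    ## per pG: plateau of minimizers; pick pG with the longest plateau
    best <- NULL
    for (pg in unique(summ$pG)) {
        sub <- summ[summ$pG == pg, ]
        if (min(sub$lambda) > lamMin) next
        mins <- sub$mCut[sub$lambda == lamMin]
        run <- .longestRun(mins, mCuts)
        if (is.null(best) || length(run) > length(best$run))
            best <- list(pG = pg, run = run)
    }
    new("GridResult",
        table = tab[, c("pG", "mCut", "type", "tauNu", "lambdaNu")],
        summary = summ,
        mCutStar = plateauMidpoint(best$run, mCuts),
        pGStar = best$pG, method = method)
}

## Internal: longest contiguous (w.r.t. grid) run of minimizers; first
## run wins ties.
.longestRun <- function(mins, grid) {
    pos <- sort(match(mins, grid))
    if (anyNA(pos)) stop("minimizers must be grid values")
    breaks <- c(0L, which(diff(pos) != 1L), length(pos))
    runs <- lapply(seq_len(length(breaks) - 1L), function(i)
        grid[pos[(breaks[i] + 1L):breaks[i + 1L]]])
    runs[[which.max(lengths(runs))]]
}

#' Midpoint of a plateau of grid minimizers
#'
#' Given the \eqn{M_{cut}} values attaining the grid minimum of
#' \eqn{\lambda}, returns the midpoint of the contiguous minimizing run:
#' e.g. the plateau (60000, 62000, 64000, 66000, 68000) yields 64000.
#' An even-length run returns the lower median; non-contiguous
#' minimizers reduce to the longest run (first on ties).
#'
#' @param mins Increasing integer vector of minimizing \eqn{M_{cut}}
#'   values.
#' @param grid The full search grid (used to judge contiguity); defaults
#'   to \code{mins} itself, i.e. the values are assumed contiguous.
#' @return The selected \eqn{M_{cut}^*}.
#' @examples
#' plateauMidpoint(c(60000, 62000, 64000, 66000, 68000))  # 64000
#' @export
plateauMidpoint <- function(mins, grid = mins) {
    if (!length(mins)) stop("empty set of minimizers")
    run <- .longestRun(mins, grid)
    run[(length(run) + 1L) %/% 2L]
}

#' Downsample a read set
#'
#' Removes exactly \eqn{\lceil r N_r \rceil} reads, chosen uniformly at
#' random without replacement, emulating loss of sequencing data. The
#' result is deterministic given \code{seed}; \code{r = 0} returns the
#' input unchanged.
#'
#' @param reads A [GenomicRanges::GRanges] of reads.
#' @param r Removal fraction in [0, 1].
#' @param seed Integer RNG seed.
#' @return A [GenomicRanges::GRanges] with
#'   \eqn{N_r - \lceil r N_r \rceil} reads (input order preserved).
#' @export
downsampleReads <- function(reads, r, seed) {
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1)
        stop("r must be a single value in [0, 1]")
    nr <- length(reads)
    k <- as.integer(ceiling(r * nr))
    if (k == 0L) return(reads)
    drop <- withSeed(seed, sample.int(nr, k))
    reads[-drop]
}

#' Penalty robustness against loss of reads
#'
#' Repeats the full pipeline at fixed \eqn{(M_{cut}, p_G)} after
#' downsampling every sample's reads by fraction \eqn{r}: downsample,
#' re-call peaks, rank, truncate, binarize, cluster, score. The
#' \eqn{r = 0} rows reproduce the baseline \eqn{\lambda} exactly (no
#' reads are removed). All samples are downsampled simultaneously within
#' a replicate, with per-sample seeds derived from \code{seed}.
#'
#' @param readsPerSample Named list of read [GenomicRanges::GRanges], one
#'   per sample.
#' @param rValues Numeric vector of removal fractions.
#' @param labels Named character vector of sample types.
#' @param peakCaller Function \code{(reads, pG) -> GRanges} with a
#'   \code{negLog10P} column, satisfying the external-caller contract
#'   (e.g. a [toyPeakCaller()] closure, or a MACS2 wrapper).
#' @param mCut,pG The fixed binarization parameters.
#' @param method Linkage method.
#' @param replicates Downsampling replicates per \eqn{r} (default 3).
#' @param seed Integer base seed.
#' @return data.frame with columns \code{r}, \code{replicate},
#'   \code{lambda}.
#' @export
robustnessCurve <- function(readsPerSample, rValues, labels, peakCaller,
                            mCut, pG, method = "ward", replicates = 3L,
                            seed = 1L) {
    ids <- names(readsPerSample)
    if (is.null(ids) || anyDuplicated(ids))
        stop("readsPerSample must be a named list with unique ids")
    rows <- list()
    for (ri in seq_along(rValues)) {
        r <- rValues[ri]
        for (rep_ in seq_len(replicates)) {
            rankedSets <- stats::setNames(vector("list", length(ids)), ids)
            for (si in seq_along(ids)) {
                sub <- if (r == 0) readsPerSample[[si]] else
                    downsampleReads(readsPerSample[[si]], r,
                                    seed = (seed + 7919L * ri +
                                            101L * rep_ + si) %% 2147483647L)
                peaks <- tryCatch(peakCaller(sub, pG),
                    error = function(e) stop(
                        "peak caller failed at r=", r, " replicate=", rep_,
                        " sample=", ids[si], ": ", conditionMessage(e),
                        call. = FALSE))
                rankedSets[[si]] <- truncatePeaks(rankPeaks(peaks, pG = pG),
                                                  mCut)
            }
            tracks <- lapply(rankedSets, binarize)
            d <- distanceMatrix(tracks, metric = "hamming")
            lam <- globalPenalty(agglomerate(d, method = method), labels)
            rows[[length(rows) + 1L]] <-
                data.frame(r = r, replicate = rep_, lambda = lam)
        }
    }
    do.call(rbind, rows)
}

## ---- GridResult accessors ----

#' @describeIn GridResult-class Per-grid-point global penalties.
#' @param x A [GridResult-class].
#' @export
setMethod("as.data.frame", "GridResult",
    function(x, ...) x@summary)

#' @describeIn GridResult-class Linkage label.
#' @export
setMethod("linkageMethod", "GridResult", function(x) x@method)

#' Selected optimum of a grid search
#'
#' @param x A [GridResult-class].
#' @return Named list with \code{mCutStar}, \code{pGStar}, \code{lambda}.
#' @export
selectedOptimum <- function(x) {
    stopifnot(is(x, "GridResult"))
    list(mCutStar = x@mCutStar, pGStar = x@pGStar,
         lambda = min(x@summary$lambda))
}

#' Per-type penalty table of a grid search
#'
#' @param x A [GridResult-class].
#' @return Long-format data.frame (pG, mCut, type, tauNu, lambdaNu).
#' @export
gridTable <- function(x) {
    stopifnot(is(x, "GridResult"))
    x@table
}

setMethod("show", "GridResult", function(object) {
    cat("GridResult (", object@method, "): ",
        nrow(object@summary), " grid points; optimum lambda = ",
        min(object@summary$lambda), " at (mCut = ", object@mCutStar,
        ", pG = ", format(object@pGStar), ")\n", sep = "")
})
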