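#' Functional-annotation profile of ranked peaks
#'
#' Slices the rank-ordered peaks into consecutive windows of
#' \code{window} peaks (window \eqn{j} covers ranks
#' \eqn{x \le k < x + window} with \eqn{x = 1 + (j-1) \cdot window}) and,
#' for each chromatin state \eqn{y}, counts the peaks whose center lies
#' inside a state interval \eqn{[\sigma, \epsilon]}:
#' \eqn{\sigma \le (\alpha_k + \beta_k)/2 \le \epsilon}, evaluated with
#' the exact integer comparison
#' \eqn{2\sigma \le \alpha_k + \beta_k \le 2\epsilon} (boundaries
#' inclusive, no rounding). Fractions always use the full window size as
#' denominator; windows extending beyond the available peaks are
#' dropped.
#'
#' @param ranked A [RankedPeakSet-class].
#' @param seg A segmentation [GenomicRanges::GRanges] with a
#'   \code{state} column (see [readChromHMM()]).
#' @param window Peaks per window (default 1000).
#' @param nWindows Maximum number of windows (default 80, i.e. the top
#'   80000 peaks).
#' @return data.frame with columns \code{windowStart} (the rank
#'   \eqn{x}), \code{state}, \code{fraction} (\eqn{|E_x^y| / window}),
#'   one row per (complete window, state) pair over the states present
#'   in \code{seg}.
#' @export
annotationProfile <- function(ranked, seg, window = 1000L,
                              nWindows = 80L) {
    stopifnot(is(ranked, "RankedPeakSet"))
    if (!is.numeric(window) || length(window) != 1L || window < 1)
        stop("window must be a positive integer")
    gr <- peakRanges(ranked)
    m <- length(gr)
    nUse <- min(nWindows, m %/% window)
    states <- sort(unique(seg$state))
    if (nUse == 0L)
        return(data.frame(windowStart = integer(0), state = character(0),
                          fraction = numeric(0)))
    gr <- gr[seq_len(nUse * window)]
    ## center rule 2*sigma <= alpha + beta <= 2*eps: the state interval
    ## must contain both floor and ceiling of the (possibly half-integer)
    ## center, i.e. the 1-2 bp range [floor(c), ceil(c)].
    c2 <- GenomicRanges::start(gr) + GenomicRanges::end(gr)
    centers <- GRanges(GenomeInfoDb::seqnames(gr),
                       IRanges::IRanges(c2 %/% 2L, (c2 + 1L) %/% 2L))
    win <- rep(seq_len(nUse), each = window)
    rows <- list()
    for (st in states) {
        sub <- seg[seg$state == st]
        hit <- suppressWarnings(
            IRanges::overlapsAny(centers, sub, type = "within"))
        counts <- tabulate(win[hit], nbins = nUse)
        rows[[st]] <- data.frame(
            windowStart = 1L + (seq_len(nUse) - 1L) * as.integer(window),
            state = st, fraction = counts / window)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$windowStart, out$state), , drop = FALSE]
}

#' Aggregate annotation profiles by cell type
#'
#' Averages per-sample annotation profiles within each cell type,
#' reporting the sample mean and sample standard deviation of the
#' fraction for every (window, state) pair (SD is 0 for a single
#' sample).
#'
#' @param profiles Named list of data.frames from [annotationProfile()];
#'   names are sample ids.
#' @param labels Named character vector of sample types.
#' @return data.frame with columns \code{type}, \code{windowStart},
#'   \code{state}, \code{mean}, \code{sd}, \code{n}.
#' @export
aggregateProfiles <- function(profiles, labels) {
    ids <- names(profiles)
    lab <- .checkLabels(labels, ids)
    long <- do.call(rbind, lapply(ids, function(id)
        cbind(profiles[[id]], sample = id, type = lab[[id]])))
    agg <- stats::aggregate(fraction ~ type + windowStart + state,
                            data = long,
                            FUN = function(x) c(mean = mean(x),
                                                sd = if (length(x) > 1L)
                                                    stats::sd(x) else 0,
                                                n = length(x)))
    out <- data.frame(type = agg$type, windowStart = agg$windowStart,
                      state = agg$state,
                      mean = agg$fraction[, "mean"],
                      sd = agg$fraction[, "sd"],
                      n = as.integer(agg$fraction[, "n"]))
    out[order(out$type, out$windowStart, out$state), , drop = FALSE]
}
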