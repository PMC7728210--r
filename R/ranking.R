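#' Rank peaks by ascending p-value
#'
#' Orders peaks so that \eqn{p_k \le p_{k'}} for \eqn{k < k'} — i.e. by
#' non-increasing \eqn{-\log_{10} p}. Ties in the score are broken by
#' genomic coordinate (chromosome order in the layout, then start, then
#' end), a stable deterministic rule across runs and platforms.
#'
#' @param peaks A [GenomicRanges::GRanges] with a \code{negLog10P}
#'   metadata column (as produced by [readNarrowPeak()]) and complete
#'   seqlengths.
#' @param pG The calling threshold the peaks came from; recorded on the
#'   result and checked against the scores (default 1 accepts any
#'   p-value).
#' @return A [RankedPeakSet-class].
#' @examples
#' layout <- genomeLayout("chr1", 1000)
#' gr <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 101, 201), width = 50),
#'     negLog10P = c(5.2, 20.4, 8.1), seqinfo = layout)
#' peakRanges(rankPeaks(gr))$negLog10P  # 20.4 8.1 5.2
#' @export
rankPeaks <- function(peaks, pG = 1) {
    if (!"negLog10P" %in% colnames(mcols(peaks)))
        stop("peaks must carry a 'negLog10P' metadata column")
    o <- order(-mcols(peaks)$negLog10P,
               as.integer(GenomeInfoDb::seqnames(peaks)),
               GenomicRanges::start(peaks),
               GenomicRanges::end(peaks))
    new("RankedPeakSet", peaks = peaks[o], pG = pG)
}

#' Truncate a ranked peak set at rank M_cut
#'
#' Returns \eqn{\bar{A}(M_{cut})}: the first \eqn{\min(M_{cut}, M)} peaks
#' in rank order. \code{mCut = Inf} keeps all peaks.
#'
#' @param ranked A [RankedPeakSet-class].
#' @param mCut Positive integer rank threshold, or \code{Inf}.
#' @return A [RankedPeakSet-class] with at most \code{mCut} peaks.
#' @export
truncatePeaks <- function(ranked, mCut) {
    stopifnot(is(ranked, "RankedPeakSet"))
    if (!is.numeric(mCut) || length(mCut) != 1L || is.na(mCut) || mCut < 1)
        stop("mCut must be a positive integer or Inf")
    n <- min(mCut, nPeaks(ranked))
    new("RankedPeakSet", peaks = ranked@peaks[seq_len(n)], pG = ranked@pG)
}

#' Binarize a ranked peak set into a genome track
#'
#' Builds the binary sequence \eqn{B = \{h_{\gamma,x}\}} whose support is
#' the union of the retained peak intervals: \eqn{h_{\gamma,x} = 1}
#' exactly when some peak satisfies \eqn{\alpha_k \le x \le \beta_k}.
#' Overlapping and abutting intervals are merged to a canonical disjoint
#' sorted representation, and positions are kept at 1-bp resolution (no
#' coarse graining). The covered length of the result is non-decreasing
#' in \eqn{M_{cut}}.
#'
#' @param ranked A [RankedPeakSet-class] (typically after
#'   [truncatePeaks()]); its peaks must carry complete seqlengths.
#' @param mCut Optional rank threshold applied before binarization
#'   (convenience for \code{binarize(truncatePeaks(ranked, mCut))}).
#' @return A [BinaryTrack-class].
#' @examples
#' layout <- genomeLayout("chr1", 1000)
#' gr <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(2, 4), c(6, 9)), negLog10P = c(9, 8),
#'     seqinfo = layout)
#' coveredLength(binarize(rankPeaks(gr)))  # 8
#' @export
binarize <- function(ranked, mCut = Inf) {
    stopifnot(is(ranked, "RankedPeakSet"))
    if (!identical(mCut, Inf)) ranked <- truncatePeaks(ranked, mCut)
    gr <- ranked@peaks
    if (anyNA(GenomeInfoDb::seqlengths(gr)))
        stop("peaks must carry complete seqlengths (use a genome layout)")
    lens <- GenomeInfoDb::seqlengths(gr)[as.character(GenomeInfoDb::seqnames(gr))]
    if (length(gr) && (any(GenomicRanges::start(gr) < 1L) ||
                       any(GenomicRanges::end(gr) > lens)))
        stop("peak outside the genome layout bounds")
    support <- GenomicRanges::reduce(GRanges(GenomeInfoDb::seqnames(gr),
                                             IRanges::ranges(gr),
                                             seqinfo = GenomeInfoDb::seqinfo(gr)))
    new("BinaryTrack", support = support,
        mCut = if (identical(mCut, Inf)) Inf else as.numeric(mCut))
}

#' Write a binary track as a sorted BED file
#'
#' Serializes the track's disjoint support intervals as 3-column BED
#' (converted back to 0-based half-open coordinates).
#'
#' @param track A [BinaryTrack-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeTrackBed <- function(track, path) {
    gr <- track@support
    df <- data.frame(as.character(GenomeInfoDb::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L,
                     GenomicRanges::end(gr))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

## ---- accessors and show methods ----

#' @describeIn RankedPeakSet-class Number of peaks \eqn{M}.
#' @param x A [RankedPeakSet-class].
#' @export
setMethod("nPeaks", "RankedPeakSet", function(x) length(x@peaks))

#' @describeIn RankedPeakSet-class The ordered peak [GenomicRanges::GRanges].
#' @export
setMethod("peakRanges", "RankedPeakSet", function(x) x@peaks)

#' @describeIn RankedPeakSet-class The calling threshold \eqn{p_G}.
#' @export
setMethod("pGThreshold", "RankedPeakSet", function(x) x@pG)

setMethod("show", "RankedPeakSet", function(object) {
    cat("RankedPeakSet with", nPeaks(object), "peaks (pG =",
        format(object@pG), ")\n")
    if (nPeaks(object)) {
        s <- mcols(object@peaks)$negLog10P
        cat("  -log10(p) range: [", format(min(s)), ",", format(max(s)), "]\n")
    }
})

#' @describeIn BinaryTrack-class The disjoint support intervals.
#' @param x A [BinaryTrack-class].
#' @export
setMethod("peakRanges", "BinaryTrack", function(x) x@support)

#' @describeIn BinaryTrack-class Total covered base pairs
#'   (\eqn{\sum (\beta - \alpha + 1)}).
#' @export
setMethod("coveredLength", "BinaryTrack",
    function(x) sum(as.numeric(GenomicRanges::width(x@support))))

#' @describeIn BinaryTrack-class The \eqn{M_{cut}} used to build the track.
#' @export
setMethod("mCutUsed", "BinaryTrack", function(x) x@mCut)

setMethod("show", "BinaryTrack", function(object) {
    cat("BinaryTrack:", length(object@support), "intervals,",
        coveredLength(object), "bp covered (mCut =",
        format(object@mCut), ")\n")
})
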