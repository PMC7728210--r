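## narrowPeak extra columns (BED6+4), per the ENCODE definition; column 8
## is -log10(p), the ranking score used throughout.
.narrowPeakCols <- c(signalValue = "numeric", pValue = "numeric",
                     qValue = "numeric", peak = "integer")

#' Read MACS2 narrowPeak peak calls
#'
#' Imports a narrowPeak (BED6+4) file and converts its 0-based half-open
#' coordinates to the package's 1-based inclusive convention: a BED line
#' \code{chr1 99 200} becomes the peak \eqn{(\alpha, \beta) = (100, 200)}.
#' Column 8 (\eqn{-\log_{10} p}) is retained as \code{negLog10P}; the
#' signal and q-value columns are ignored. Peaks on chromosomes absent
#' from the layout, or outside chromosome bounds, are rejected with an
#' error.
#'
#' @param path Path to a narrowPeak file.
#' @param layout Genome layout ([GenomeInfoDb::Seqinfo]) the peaks must
#'   lie within.
#' @return A [GenomicRanges::GRanges] with a \code{negLog10P} metadata
#'   column, in file order.
#' @examples
#' layout <- genomeLayout("chr1", 100000)
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t99\t200\t.\t0\t.\t5.0\t8.19\t6.0\t50", f)
#' p <- readNarrowPeak(f, layout)
#' GenomicRanges::start(p)  # 100
#' @export
readNarrowPeak <- function(path, layout) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0L) {
        gr0 <- GRanges()
        mcols(gr0)$negLog10P <- numeric(0)
        return(.withLayout(gr0, layout))
    }
    gr <- tryCatch(
        rtracklayer::import(path, format = "BED",
                            extraCols = .narrowPeakCols),
        error = function(e) stop("narrowPeak parse error in '", path,
                                 "': ", conditionMessage(e), call. = FALSE))
    if (any(GenomicRanges::width(gr) < 1L))
        stop("narrowPeak parse error in '", path, "': line with end <= start ",
             "(first at record ", which(GenomicRanges::width(gr) < 1L)[1], ")")
    if (anyNA(gr$pValue) || any(gr$pValue < 0))
        stop("narrowPeak parse error in '", path,
             "': column 8 (-log10 p) must be non-negative")
    out <- GRanges(GenomeInfoDb::seqnames(gr), IRanges::ranges(gr),
                   negLog10P = gr$pValue)
    .withLayout(out, layout)
}

#' Write peaks as a narrowPeak file
#'
#' Converts back to 0-based half-open BED coordinates (the inverse of
#' [readNarrowPeak()], so a write/read round trip is the identity) and
#' emits the ten narrowPeak columns with \code{negLog10P} in column 8.
#' Unused columns are filled with the conventional placeholders.
#'
#' @param peaks A [GenomicRanges::GRanges] with \code{negLog10P}, or a
#'   [RankedPeakSet-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeNarrowPeak <- function(peaks, path) {
    if (is(peaks, "RankedPeakSet")) peaks <- peakRanges(peaks)
    df <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(peaks)),
        start = GenomicRanges::start(peaks) - 1L,
        end = GenomicRanges::end(peaks),
        name = ".", score = 0L, strand = ".",
        signalValue = 0,
        pValue = mcols(peaks)$negLog10P,
        qValue = -1, peak = -1L)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Peak width as reported by the method
#'
#' Returns \eqn{\beta_k - \alpha_k} for each peak — the end minus start
#' difference, not the number of covered positions (which is
#' \eqn{\beta - \alpha + 1} and is what [coveredLength()] accounts).
#' A 1-bp peak therefore has width 0.
#'
#' @param peaks A [GenomicRanges::GRanges] or [RankedPeakSet-class].
#' @return Integer vector of widths in bp.
#' @examples
#' p <- GenomicRanges::GRanges("chr3", IRanges::IRanges(188271079, 188271985))
#' peakWidth(p)  # 906
#' @export
peakWidth <- function(peaks) {
    if (is(peaks, "RankedPeakSet")) peaks <- peakRanges(peaks)
    GenomicRanges::end(peaks) - GenomicRanges::start(peaks)
}

#' Read aligned read positions from a 3-column BED file
#'
#' Reads analysis-ready read positions (post alignment, deduplication and
#' mapping-quality filtering, which are prerequisites handled upstream)
#' as 1-based inclusive intervals.
#'
#' @param path Path to a BED (or tagAlign-like) file; only the first three
#'   columns are used.
#' @param layout Genome layout the reads must lie within.
#' @return A [GenomicRanges::GRanges] of reads.
#' @export
readReadsBed <- function(path, layout) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0L) return(.withLayout(GRanges(), layout))
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) stop("BED parse error in '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
    out <- GRanges(GenomeInfoDb::seqnames(gr), IRanges::ranges(gr))
    .withLayout(out, layout)
}

#' Write read positions as a 3-column BED file
#'
#' @param reads A [GenomicRanges::GRanges] of reads.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeReadsBed <- function(reads, path) {
    df <- data.frame(as.character(GenomeInfoDb::seqnames(reads)),
                     GenomicRanges::start(reads) - 1L,
                     GenomicRanges::end(reads))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a sample-to-cell-type label table
#'
#' Reads the 2-column TSV (sample id, type) that defines the labeled
#' cohort: the partition \eqn{S = \bigcup_\nu S_\nu} of samples into cell
#' types used by the penalty and classification steps.
#'
#' @param path Path to the TSV file (no header).
#' @return Named character vector: names are sample ids, values are type
#'   labels.
#' @export
readLabels <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("sample", "type"),
                             colClasses = "character")
    if (anyDuplicated(tab$sample))
        stop("duplicate sample ids in label table")
    stats::setNames(tab$type, tab$sample)
}

## Internal: validate a label vector against a set of sample ids.
.checkLabels <- function(labels, samples) {
    if (is.null(names(labels)) || anyDuplicated(names(labels)))
        stop("labels must be a named vector with unique sample ids")
    missing <- setdiff(samples, names(labels))
    if (length(missing))
        stop("no type label for sample(s): ", paste(missing, collapse = ", "))
    labels[samples]
}
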