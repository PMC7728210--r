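#' Hamming distance between two binary tracks
#'
#' The Hamming distance
#' \eqn{H(B^a, B^b) = \sum_{\gamma, x} \delta(h^a_{\gamma,x},
#' h^b_{\gamma,x})} is the number of genomic positions where the two
#' tracks differ. It is computed exactly on the interval representations
#' by inclusion–exclusion,
#' \eqn{H = |a| + |b| - 2\,|a \cap b|} (with \eqn{|\cdot|} the covered
#' length), so genome-length vectors are never materialized. The result
#' is an exact integer number of base pairs.
#'
#' @param a,b [BinaryTrack-class] objects on the same genome layout.
#' @return Non-negative numeric (integer-valued) distance in bp.
#' @examples
#' layout <- genomeLayout("chr1", 1000)
#' t1 <- binarize(rankPeaks(GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(1, 10), negLog10P = 5, seqinfo = layout)))
#' t2 <- binarize(rankPeaks(GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(6, 15), negLog10P = 5, seqinfo = layout)))
#' hammingDistance(t1, t2)  # 10
#' @export
hammingDistance <- function(a, b) {
    stopifnot(is(a, "BinaryTrack"), is(b, "BinaryTrack"))
    if (!.sameLayout(a@support, b@support))
        stop("tracks are on different genome layouts")
    inter <- GenomicRanges::intersect(a@support, b@support)
    coveredLength(a) + coveredLength(b) -
        2 * sum(as.numeric(GenomicRanges::width(inter)))
}

#' Dice coefficient between two binary tracks
#'
#' The overlap similarity
#' \eqn{\mathrm{Dice}(a, b) = 2|a \cap b| / (|a| + |b|)} in [0, 1]:
#' 1 for identical non-empty tracks, 0 for disjoint supports. Its
#' complement \eqn{1 - \mathrm{Dice}} serves as an alternative
#' dissimilarity for the clustering engine (see
#' [distanceMatrix()] with \code{metric = "dice"}).
#'
#' @inheritParams hammingDistance
#' @return Numeric in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
    stopifnot(is(a, "BinaryTrack"), is(b, "BinaryTrack"))
    if (!.sameLayout(a@support, b@support))
        stop("tracks are on different genome layouts")
    tot <- coveredLength(a) + coveredLength(b)
    if (tot == 0)
        stop("Dice coefficient is undefined when both tracks are empty")
    inter <- GenomicRanges::intersect(a@support, b@support)
    2 * sum(as.numeric(GenomicRanges::width(inter))) / tot
}

## Internal: distance between two tracks under a metric label.
.trackDistance <- function(a, b, metric) {
    switch(metric,
           hamming = hammingDistance(a, b),
           dice = 1 - diceCoefficient(a, b),
           stop("unknown metric: ", metric))
}

#' Pairwise distance matrix over a set of binary tracks
#'
#' Computes all unordered pairs once and assembles the symmetric matrix
#' \eqn{d_{ij}} used as input to [agglomerate()]. Hamming distances are
#' exact integers in bp; \code{metric = "dice"} gives the
#' \eqn{1 - \mathrm{Dice}} dissimilarity instead.
#'
#' @param tracks Named list of [BinaryTrack-class] objects on one layout;
#'   names are the sample ids and must be unique.
#' @param metric \code{"hamming"} (default) or \code{"dice"}.
#' @return A [TrackDistanceMatrix-class].
#' @export
distanceMatrix <- function(tracks, metric = c("hamming", "dice")) {
    metric <- match.arg(metric)
    ids <- names(tracks)
    if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
        stop("tracks must be a named list with unique, non-empty sample ids")
    n <- length(tracks)
    if (n < 2L) stop("at least two samples are required")
    v <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L))
        for (j in seq((i + 1L), n)) {
            v[i, j] <- .trackDistance(tracks[[i]], tracks[[j]], metric)
            v[j, i] <- v[i, j]
        }
    mcuts <- unique(vapply(tracks, function(t) t@mCut, numeric(1)))
    new("TrackDistanceMatrix", values = v, metric = metric,
        mCut = if (length(mcuts) == 1L) mcuts else NA_real_, pG = NA_real_)
}

#' Extend a distance matrix with new samples
#'
#' Implements the low-cost incremental case: when new samples join an
#' analyzed cohort, only the distances involving new samples are
#' computed; the existing block is copied untouched.
#'
#' @param d A [TrackDistanceMatrix-class] over the existing samples.
#' @param tracks Named list of the existing samples' tracks (those in
#'   \code{d}).
#' @param newTracks Named list of the tracks to add; ids must not collide
#'   with existing ones.
#' @return A [TrackDistanceMatrix-class] over the union of samples.
#' @export
extendDistanceMatrix <- function(d, tracks, newTracks) {
    stopifnot(is(d, "TrackDistanceMatrix"))
    ids <- rownames(d@values)
    if (!setequal(ids, names(tracks)))
        stop("'tracks' must cover exactly the samples already in the matrix")
    newIds <- names(newTracks)
    if (is.null(newIds) || anyDuplicated(newIds) ||
        any(newIds %in% ids))
        stop("new sample ids must be unique and distinct from existing ones")
    all <- c(ids, newIds)
    n0 <- length(ids); n <- length(all)
    v <- matrix(0, n, n, dimnames = list(all, all))
    v[seq_len(n0), seq_len(n0)] <- d@values[ids, ids]
    for (j in seq_along(newIds)) {
        for (i in seq_len(n0)) {
            val <- .trackDistance(tracks[[ids[i]]], newTracks[[j]], d@metric)
            v[i, n0 + j] <- val; v[n0 + j, i] <- val
        }
        if (j > 1L) for (k in seq_len(j - 1L)) {
            val <- .trackDistance(newTracks[[k]], newTracks[[j]], d@metric)
            v[n0 + k, n0 + j] <- val; v[n0 + j, n0 + k] <- val
        }
    }
    new("TrackDistanceMatrix", values = v, metric = d@metric,
        mCut = d@mCut, pG = d@pG)
}

#' Construct a distance matrix from precomputed values
#'
#' Wraps an externally computed symmetric matrix (e.g. read back from
#' TSV) in the class the clustering engine accepts.
#'
#' @param values Symmetric numeric matrix with dimnames.
#' @param metric Metric label.
#' @param mCut,pG Optional parameter provenance.
#' @return A [TrackDistanceMatrix-class].
#' @export
asTrackDistanceMatrix <- function(values, metric = "hamming",
                                  mCut = NA_real_, pG = NA_real_) {
    new("TrackDistanceMatrix", values = values, metric = metric,
        mCut = mCut, pG = pG)
}

#' Write / read a labeled square distance matrix as TSV
#'
#' @param d A [TrackDistanceMatrix-class].
#' @param path File path.
#' @return \code{writeDistanceMatrix}: invisibly, \code{path};
#'   \code{readDistanceMatrix}: a [TrackDistanceMatrix-class].
#' @export
writeDistanceMatrix <- function(d, path) {
    utils::write.table(d@values, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
    invisible(path)
}

#' @rdname writeDistanceMatrix
#' @param metric Metric label to record on the read matrix.
#' @export
readDistanceMatrix <- function(path, metric = "hamming") {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    asTrackDistanceMatrix(m, metric = metric)
}

#' Export the lower triangle in PHYLIP format
#'
#' @param d A [TrackDistanceMatrix-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writePhylip <- function(d, path) {
    v <- d@values
    n <- nrow(v)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", n), con)
    for (i in seq_len(n)) {
        row <- if (i > 1L) paste(format(v[i, seq_len(i - 1L)], trim = TRUE),
                                 collapse = "\t") else ""
        writeLines(paste(rownames(v)[i], row, sep = "\t"), con)
    }
    invisible(path)
}

## ---- accessors ----

#' @describeIn TrackDistanceMatrix-class The sample ids (row order).
#' @param x A [TrackDistanceMatrix-class].
#' @export
setMethod("sampleIds", "TrackDistanceMatrix", function(x) rownames(x@values))

#' @describeIn TrackDistanceMatrix-class The raw symmetric matrix.
#' @export
setMethod("as.matrix", "TrackDistanceMatrix", function(x) x@values)

setMethod("show", "TrackDistanceMatrix", function(object) {
    cat("TrackDistanceMatrix (", object@metric, ") over ",
        nrow(object@values), " samples\n", sep = "")
})
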