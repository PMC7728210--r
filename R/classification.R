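#' Ward set distances from a query sample to every reference type
#'
#' For a query sample \eqn{\zeta} binarized at the same
#' \eqn{(M_{cut}, p_G)} as the references, computes
#' \eqn{H_{Ward}(\{\zeta\}, S_\nu)} for every reference cell type
#' \eqn{\nu}. Only the \eqn{N_{ref}} new Hamming distances involving the
#' query are computed; the reference-to-reference block is reused from
#' (or cached into) a distance matrix, honoring the incremental-cost
#' contract. Empty reference types are skipped with a warning.
#'
#' @param query A [BinaryTrack-class] for the query sample.
#' @param refTracks Named list of reference [BinaryTrack-class] objects.
#' @param labels Named character vector of reference sample types.
#' @param refMatrix Optional precomputed [TrackDistanceMatrix-class]
#'   over the reference samples (computed once here if missing).
#' @return Named numeric vector: Ward set distance per type (unsorted).
#' @export
typeDistances <- function(query, refTracks, labels, refMatrix = NULL) {
    ids <- names(refTracks)
    lab <- .checkLabels(labels, ids)
    if (is.null(refMatrix))
        refMatrix <- distanceMatrix(refTracks, metric = "hamming")
    v <- as.matrix(refMatrix)[ids, ids, drop = FALSE]
    ## the only new distances: query vs each reference
    dq <- vapply(refTracks, function(t) hammingDistance(query, t),
                 numeric(1))
    types <- sort(unique(lab))
    out <- stats::setNames(rep(NA_real_, length(types)), types)
    for (tp in types) {
        members <- ids[lab == tp]
        n2 <- length(members)
        if (!n2) { warning("empty reference type: ", tp); next }
        D2 <- sum(v[members, members]^2) / 2
        D12 <- sum(dq[members]^2)
        Q <- D12 / (1 + n2) - D2 / (n2 * (1 + n2))
        out[tp] <- sqrt(max(Q, 0))
    }
    out[!is.na(out)]
}

#' Rank reference types by closeness to a query
#'
#' Sorts the per-type Ward distances ascending; the q-th entry is the
#' q-th closest type \eqn{\nu_\zeta^{(q)}}. Ties are broken
#' alphabetically by type label.
#'
#' @param distances Named numeric vector from [typeDistances()].
#' @return data.frame with columns \code{rank}, \code{type},
#'   \code{distance} (distances non-decreasing down the rows).
#' @export
closestTypes <- function(distances) {
    if (!length(distances)) stop("empty distance mapping")
    o <- order(distances, names(distances))
    data.frame(rank = seq_along(distances),
               type = names(distances)[o],
               distance = unname(distances[o]))
}

#' Rank gap of a reference type in a type ranking
#'
#' If reference type \eqn{T_0} is the q-th closest type of the query,
#' the rank gap is \eqn{G_{T_0,\zeta} = q - 1}: 0 when \eqn{T_0} is the
#' closest type, 1 when it is second, and so on.
#'
#' @param ranking data.frame from [closestTypes()].
#' @param type The reference type \eqn{T_0}.
#' @return Non-negative integer.
#' @export
rankGap <- function(ranking, type) {
    q <- ranking$rank[ranking$type == type]
    if (!length(q)) stop("type not present in ranking: ", type)
    q[1] - 1L
}

#' Classify a query sample against reference cell types
#'
#' End-to-end convenience wrapper: binarizes the query's ranked peaks at
#' \eqn{(M_{cut}, p_G)}, computes Ward set distances to every reference
#' type, and returns the full type ranking (plus the rank gap against an
#' expected type, if given). Query samples are never added to the
#' reference sets; batch queries are independent.
#'
#' @param queryPeaks A [RankedPeakSet-class] for the query (or an
#'   already-binarized [BinaryTrack-class]).
#' @param refTracks Named list of reference [BinaryTrack-class] objects
#'   binarized at the same parameters.
#' @param labels Named character vector of reference sample types.
#' @param mCut Rank threshold applied to the query peaks (ignored for a
#'   pre-binarized query).
#' @param refMatrix Optional cached reference distance matrix.
#' @param expectedType Optional reference type \eqn{T_0} to report a
#'   rank gap for.
#' @return List with \code{ranking} (data.frame), \code{closestType},
#'   and \code{rankGap} (\code{NA} when no expected type is given).
#' @export
classifySample <- function(queryPeaks, refTracks, labels, mCut = Inf,
                           refMatrix = NULL, expectedType = NULL) {
    query <- if (is(queryPeaks, "BinaryTrack")) queryPeaks
             else binarize(queryPeaks, mCut = mCut)
    dists <- typeDistances(query, refTracks, labels, refMatrix)
    ranking <- closestTypes(dists)
    list(ranking = ranking,
         closestType = ranking$type[1],
         rankGap = if (is.null(expectedType)) NA_integer_
                   else rankGap(ranking, expectedType))
}
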