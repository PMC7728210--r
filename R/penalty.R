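#' Type penalty of a labeled dendrogram
#'
#' For cell type \eqn{\nu}, finds \eqn{\tau(\nu)}: the minimum historical
#' cluster index \eqn{\tau} such that \eqn{S_\nu \subseteq C_\tau} (the
#' first cluster, in creation order, containing every sample of the
#' type; the root guarantees existence). The type penalty is the number
#' of foreign samples swept up,
#' \deqn{\lambda_\nu = |C_{\tau(\nu)}| - |S_\nu|,}
#' with \eqn{\lambda_\nu = 0} for an empty \eqn{S_\nu}. It satisfies
#' \eqn{0 \le \lambda_\nu \le |S| - |S_\nu|}.
#'
#' @param dendro A [PeakDendrogram-class].
#' @param labels Named character vector mapping every leaf label to its
#'   cell type (see [readLabels()]).
#' @param type The cell type \eqn{\nu} to score.
#' @return List with elements \code{lambda} (integer penalty) and
#'   \code{tau} (the index \eqn{\tau(\nu)}, \code{NA} for an empty type).
#' @export
typePenalty <- function(dendro, labels, type) {
    stopifnot(is(dendro, "PeakDendrogram"))
    lab <- .checkLabels(labels, dendro@labels)
    if (!type %in% lab && !type %in% labels)
        stop("unknown type: ", type)
    members <- which(lab == type)
    if (!length(members)) return(list(lambda = 0L, tau = NA_integer_))
    for (tau in seq_along(dendro@clusters)) {
        ctau <- dendro@clusters[[tau]]
        if (all(members %in% ctau))
            return(list(lambda = length(ctau) - length(members),
                        tau = tau))
    }
    stop("internal error: root does not contain all samples")  # unreachable
}

#' Global penalty of a labeled dendrogram
#'
#' The cost function of the method: the sum of type penalties over all
#' cell types, \eqn{\lambda = \sum_\nu \lambda_\nu}. A perfectly
#' classified dendrogram — every \eqn{S_\nu} coincides with an offspring
#' set — gives \eqn{\lambda = 0}; the upper bound is
#' \eqn{(|\mathbb{T}| - 1) \cdot |S|} (see [penaltyBounds()]). The
#' penalty depends only on the merge topology and order, so it is
#' invariant under monotone transformations of the heights.
#'
#' @inheritParams typePenalty
#' @return Integer global penalty \eqn{\lambda}.
#' @export
globalPenalty <- function(dendro, labels) {
    report <- penaltyReport(dendro, labels)
    sum(report$lambdaNu)
}

#' Per-type penalty report
#'
#' @inheritParams typePenalty
#' @return data.frame with one row per type present in \code{labels}:
#'   \code{type}, \code{tauNu}, \code{lambdaNu}.
#' @export
penaltyReport <- function(dendro, labels) {
    lab <- .checkLabels(labels, dendro@labels)
    types <- sort(unique(lab))
    rows <- lapply(types, function(tp) {
        p <- typePenalty(dendro, labels, tp)
        data.frame(type = tp, tauNu = p$tau, lambdaNu = p$lambda)
    })
    do.call(rbind, rows)
}

#' Analytic penalty bounds of a labeled cohort
#'
#' Returns the attainable range of the global penalty for a cohort with
#' type set \eqn{\mathbb{T}} over samples \eqn{S}:
#' \deqn{0 \le \lambda \le \sum_\nu (|S| - |S_\nu|)
#'       = (|\mathbb{T}| - 1) \cdot |S|.}
#'
#' @param labels Named character vector of sample types, or a list with
#'   elements \code{nTypes} and \code{nSamples} for the analytic case.
#' @return Named numeric vector \code{c(lower, upper)}.
#' @examples
#' penaltyBounds(list(nTypes = 13, nSamples = 77))  # upper = 924
#' @export
penaltyBounds <- function(labels) {
    if (is.list(labels)) {
        nT <- labels$nTypes; nS <- labels$nSamples
    } else {
        nT <- length(unique(labels)); nS <- length(labels)
    }
    c(lower = 0, upper = (nT - 1) * nS)
}
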