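#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' RankedPeakSet: p-value-ordered peak calls for one sample
#'
#' A set of called peaks for a single sample, ordered by ascending
#' peak-calling p-value (equivalently, by non-increasing \code{negLog10P}).
#' Coordinates are 1-based inclusive throughout the package; the peak
#' \eqn{g_k = (\gamma_k, \alpha_k, \beta_k)} occupies every position
#' \eqn{\alpha_k \le x \le \beta_k}.
#'
#' @slot peaks A [GenomicRanges::GRanges] with a numeric \code{negLog10P}
#'   metadata column, sorted so that \code{negLog10P} is non-increasing.
#' @slot pG The peak-calling significance threshold \eqn{p_G} in (0, 1];
#'   every retained peak satisfies \eqn{p_k \le p_G}.
#' @seealso [rankPeaks()], [truncatePeaks()], [binarize()]
#' @export
setClass("RankedPeakSet",
    representation(peaks = "GRanges", pG = "numeric"))

setValidity("RankedPeakSet", function(object) {
    msg <- character()
    gr <- object@peaks
    if (!"negLog10P" %in% colnames(mcols(gr)))
        msg <- c(msg, "peaks must carry a 'negLog10P' metadata column")
    else {
        s <- mcols(gr)$negLog10P
        if (anyNA(s) || any(s < 0))
            msg <- c(msg, "negLog10P must be non-negative and non-missing")
        if (length(s) > 1L && any(diff(s) > 1e-12))
            msg <- c(msg, "peaks must be ordered by non-increasing negLog10P")
        if (length(s) && min(s) < -log10(object@pG) - 1e-9)
            msg <- c(msg, "every peak must satisfy p_k <= p_G")
    }
    if (length(object@pG) != 1L || is.na(object@pG) ||
        object@pG <= 0 || object@pG > 1)
        msg <- c(msg, "pG must be a single value in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' BinaryTrack: a binarized genome as disjoint intervals
#'
#' The binary sequence \eqn{B = \{h_{\gamma,x}\}} of one sample:
#' \eqn{h_{\gamma,x} = 1} exactly when position \eqn{x} of chromosome
#' \eqn{\gamma} lies inside a retained peak. The support is stored as
#' disjoint, sorted, 1-based inclusive intervals per chromosome — never as
#' a per-position vector — so genome-scale tracks stay small.
#'
#' @slot support A reduced (disjoint, sorted, adjacency-merged)
#'   [GenomicRanges::GRanges] with complete \code{seqlengths}.
#' @slot mCut The rank threshold used to build the track (\code{Inf} when
#'   all peaks were kept).
#' @seealso [binarize()], [coveredLength()], [hammingDistance()]
#' @export
setClass("BinaryTrack",
    representation(support = "GRanges", mCut = "numeric"))

setValidity("BinaryTrack", function(object) {
    msg <- character()
    gr <- object@support
    if (anyNA(GenomeInfoDb::seqlengths(gr)))
        msg <- c(msg, "support must carry complete seqlengths (the genome layout)")
    red <- GenomicRanges::reduce(gr)
    if (length(red) != length(gr) ||
        (length(gr) && !all(red == sort(gr))))
        msg <- c(msg, "support intervals must be disjoint, sorted and adjacency-merged")
    if (length(object@mCut) != 1L || is.na(object@mCut) || object@mCut < 1)
        msg <- c(msg, "mCut must be a single value >= 1 (possibly Inf)")
    if (length(msg)) msg else TRUE
})

#' TrackDistanceMatrix: pairwise distances between binary tracks
#'
#' Symmetric matrix of pairwise distances \eqn{d_{ij}} between samples'
#' binary tracks, either Hamming distances (integer base pairs) or Dice
#' dissimilarities \eqn{1 - \mathrm{Dice}} (unitless in [0, 1]), together
#' with the \eqn{(M_{cut}, p_G)} parameters the tracks were built with.
#'
#' @slot values Symmetric numeric matrix with zero diagonal; dimnames are
#'   the sample identifiers.
#' @slot metric Either \code{"hamming"} or \code{"dice"}.
#' @slot mCut,pG Parameters recorded from the tracks (\code{NA} when mixed
#'   or unknown).
#' @seealso [distanceMatrix()], [extendDistanceMatrix()]
#' @export
setClass("TrackDistanceMatrix",
    representation(values = "matrix", metric = "character",
                   mCut = "numeric", pG = "numeric"))

setValidity("TrackDistanceMatrix", function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v) || nrow(v) != ncol(v))
        msg <- c(msg, "values must be a square numeric matrix")
    else {
        if (is.null(rownames(v)) || anyDuplicated(rownames(v)) ||
            !identical(rownames(v), colnames(v)))
            msg <- c(msg, "values must have identical, unique row and column names")
        if (any(abs(v - t(v)) > 1e-9)) msg <- c(msg, "values must be symmetric")
        if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
        if (any(v < 0)) msg <- c(msg, "distances must be non-negative")
    }
    if (!object@metric %in% c("hamming", "dice"))
        msg <- c(msg, "metric must be 'hamming' or 'dice'")
    if (length(msg)) msg else TRUE
})

#' PeakDendrogram: agglomerative clustering with full cluster history
#'
#' The result of agglomerative hierarchical clustering over \eqn{N_s}
#' samples: the historical list of \eqn{2N_s - 1} clusters
#' \eqn{C_1, \ldots, C_{2N_s-1}} (leaves first, then one new cluster per
#' merge, each with an ordered member sequence), and the \eqn{N_s - 1}
#' merge records. Cluster \eqn{C_{t+N_s}} is the union of the merged pair,
#' ordered as the first cluster's members followed by the second's.
#'
#' @slot labels Character vector of the \eqn{N_s} sample identifiers, in
#'   leaf-index order (leaf \eqn{\tau} is \code{labels[tau]}).
#' @slot merges A data.frame with one row per merge step \eqn{t}: columns
#'   \code{step}, \code{tau1}, \code{tau2} (historical cluster indices,
#'   \code{tau1 < tau2}), \code{height} (the merging set distance) and
#'   \code{rawQ} (for Ward, the unrooted bracketed quantity \eqn{Q} whose
#'   square root is the height; \code{NA} otherwise).
#' @slot clusters List of length \eqn{2N_s - 1}; element \eqn{\tau} is the
#'   ordered integer vector of leaf indices in \eqn{C_\tau}.
#' @slot method Linkage label: one of \code{"ward"}, \code{"upgma"},
#'   \code{"wpgma"}, \code{"upgmc"}, \code{"wpgmc"}, or \code{"imported"}
#'   for dendrograms rebuilt from a merge table.
#' @seealso [agglomerate()], [offspring()], [nodeCoordinates()],
#'   [globalPenalty()]
#' @export
setClass("PeakDendrogram",
    representation(labels = "character", merges = "data.frame",
                   clusters = "list", method = "character"))

setValidity("PeakDendrogram", function(object) {
    msg <- character()
    ns <- length(object@labels)
    if (ns < 2L) msg <- c(msg, "at least two samples are required")
    if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
    if (length(object@clusters) != 2L * ns - 1L)
        msg <- c(msg, "clusters must have length 2*Ns - 1")
    if (nrow(object@merges) != ns - 1L)
        msg <- c(msg, "merges must have Ns - 1 rows")
    if (!all(c("step", "tau1", "tau2", "height", "rawQ") %in%
             colnames(object@merges)))
        msg <- c(msg, "merges must have columns step, tau1, tau2, height, rawQ")
    if (!length(msg)) {
        for (tau in seq_len(ns))
            if (!identical(object@clusters[[tau]], tau))
                msg <- c(msg, "leaf clusters C_tau must equal {tau}")
        for (t in seq_len(ns - 1L)) {
            t1 <- object@merges$tau1[t]; t2 <- object@merges$tau2[t]
            if (!(t1 < t2 && t2 < t + ns))
                msg <- c(msg, "merge indices must satisfy tau1 < tau2 < t + Ns")
            else if (!identical(object@clusters[[t + ns]],
                                c(object@clusters[[t1]], object@clusters[[t2]])))
                msg <- c(msg, "merged cluster order must be C_tau1 then C_tau2")
        }
        root <- object@clusters[[2L * ns - 1L]]
        if (!setequal(root, seq_len(ns)))
            msg <- c(msg, "the final cluster must contain every sample")
    }
    if (length(msg)) msg else TRUE
})

#' GridResult: penalty landscape of the (M_cut, p_G) grid search
#'
#' @slot table Long-format data.frame with one row per (pG, mCut, type):
#'   columns \code{pG}, \code{mCut}, \code{type}, \code{lambdaNu},
#'   \code{tauNu}.
#' @slot summary data.frame with one row per grid point: \code{pG},
#'   \code{mCut}, \code{lambda}.
#' @slot mCutStar,pGStar The selected optimum (plateau midpoint rule).
#' @slot method Linkage method used.
#' @seealso [gridSearch()], [plateauMidpoint()]
#' @export
setClass("GridResult",
    representation(table = "data.frame", summary = "data.frame",
                   mCutStar = "numeric", pGStar = "numeric",
                   method = "character"))

setValidity("GridResult", function(object) {
    msg <- character()
    s <- object@summary
    if (!all(c("pG", "mCut", "lambda") %in% colnames(s)))
        msg <- c(msg, "summary must have columns pG, mCut, lambda")
    else {
        sel <- s$lambda[s$mCut == object@mCutStar & s$pG == object@pGStar]
        if (!length(sel) || abs(min(s$lambda) - sel[1]) > 1e-9)
            msg <- c(msg, "the selected point must attain the grid minimum")
    }
    if (length(msg)) msg else TRUE
})
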