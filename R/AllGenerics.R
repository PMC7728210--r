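#' @include AllClasses.R
NULL

#' Number of peaks, samples or intervals in an object
#'
#' @param x A PeakHamming object.
#' @return An integer count.
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))

#' Total number of genomic positions with h = 1
#'
#' The covered length of a binary track: the number of base pairs
#' \eqn{(\gamma, x)} with \eqn{h_{\gamma,x} = 1}, i.e. the sum of
#' \eqn{\beta - \alpha + 1} over its disjoint support intervals.
#'
#' @param x A [BinaryTrack-class].
#' @return Numeric count of base pairs.
#' @export
setGeneric("coveredLength", function(x) standardGeneric("coveredLength"))

#' Extract the underlying GRanges of peaks or support intervals
#'
#' @param x A [RankedPeakSet-class] or [BinaryTrack-class].
#' @return A [GenomicRanges::GRanges].
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' The p_G calling threshold recorded in an object
#'
#' @param x An object carrying a \eqn{p_G} value.
#' @return A numeric scalar in (0, 1].
#' @export
setGeneric("pGThreshold", function(x) standardGeneric("pGThreshold"))

#' The M_cut rank threshold recorded in an object
#'
#' @param x An object carrying an \eqn{M_{cut}} value.
#' @return A numeric scalar (possibly \code{Inf}).
#' @export
setGeneric("mCutUsed", function(x) standardGeneric("mCutUsed"))

#' Offspring set of a dendrogram node
#'
#' Returns the offspring set \eqn{\mathbb{B}_n} of node \eqn{\tau}: the
#' cluster \eqn{C_\tau} as an unordered set of sample labels. Leaves
#' (\eqn{\tau \le N_s}) give singletons; the root gives every sample.
#'
#' @param x A [PeakDendrogram-class].
#' @param tau Historical cluster index in \eqn{1 \ldots 2N_s - 1}.
#' @return Character vector of sample labels.
#' @examples
#' d <- dendrogramFromMerges(c("a", "b", "c"),
#'     data.frame(tau1 = c(1, 4), tau2 = c(2, 3), height = c(1, 2)))
#' offspring(d, 4)  # c("a", "b")
#' @export
setGeneric("offspring", function(x, tau) standardGeneric("offspring"))

#' Merge records of a dendrogram
#'
#' @param x A [PeakDendrogram-class].
#' @return A data.frame with columns \code{step}, \code{tau1}, \code{tau2},
#'   \code{height}, \code{rawQ}.
#' @export
setGeneric("mergeTable", function(x) standardGeneric("mergeTable"))

#' Linkage method label of a clustering
#'
#' @param x A [PeakDendrogram-class] or [GridResult-class].
#' @return Character scalar.
#' @export
setGeneric("linkageMethod", function(x) standardGeneric("linkageMethod"))

#' Sample identifiers of an object
#'
#' @param x A PeakHamming object with named samples.
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
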