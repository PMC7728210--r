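## Linkage methods. "ward" and "upgma" follow the explicit set-distance
## definitions (see setDistanceWard / setDistanceUPGMA); the other three
## are the standard Lance-Williams variants, with the centroid methods
## (upgmc, wpgmc) operating on squared distances.
.linkageMethods <- c("ward", "upgma", "wpgma", "upgmc", "wpgmc")

## Internal: resolve member arguments (labels or indices) to integer
## indices into a distance matrix.
.resolveMembers <- function(members, ids) {
    if (is.character(members)) {
        idx <- match(members, ids)
        if (anyNA(idx))
            stop("unknown sample(s): ",
                 paste(members[is.na(idx)], collapse = ", "))
        idx
    } else as.integer(members)
}

.distValues <- function(d) {
    if (is(d, "TrackDistanceMatrix")) d@values
    else if (is.matrix(d)) d
    else stop("'d' must be a TrackDistanceMatrix or a symmetric matrix")
}

#' UPGMA set distance between two clusters
#'
#' The average of all pairwise sample distances across the two clusters,
#' \deqn{H_{UPGMA}(C_1, C_2) = \frac{1}{|C_1||C_2|} \sum_{c_1 \in C_1}
#' \sum_{c_2 \in C_2} d_{c_1 c_2}.}
#' By convention the distance is 0 when either cluster is empty. For two
#' singletons it equals the sample distance itself (\eqn{K = 1}).
#'
#' @param c1,c2 Disjoint member sets: sample labels or integer indices
#'   into \code{d}.
#' @param d A [TrackDistanceMatrix-class] or symmetric numeric matrix.
#' @return Non-negative numeric set distance.
#' @export
setDistanceUPGMA <- function(c1, c2, d) {
    v <- .distValues(d)
    i1 <- .resolveMembers(c1, rownames(v))
    i2 <- .resolveMembers(c2, rownames(v))
    if (!length(i1) || !length(i2)) return(0)
    if (length(intersect(i1, i2)))
        stop("clusters must be disjoint")
    mean(v[i1, i2, drop = FALSE])
}

#' Ward set distance between two clusters
#'
#' Evaluates the bracketed Ward quantity built from squared sample
#' distances,
#' \deqn{Q = \frac{D_{1,2}}{|C_1|+|C_2|}
#'       - \frac{|C_2|\,D_1}{|C_1|(|C_1|+|C_2|)}
#'       - \frac{|C_1|\,D_2}{|C_2|(|C_1|+|C_2|)},}
#' with \eqn{D_1 = \frac12 \sum_{C_1 \times C_1} d^2},
#' \eqn{D_2 = \frac12 \sum_{C_2 \times C_2} d^2} and
#' \eqn{D_{1,2} = \sum_{C_1 \times C_2} d^2}, and returns
#' \eqn{\sqrt{\max(Q, 0)}}. The square root makes the singleton identity
#' \eqn{H(\{c_1\}, \{c_2\}) = 2^{-1/2} d} hold exactly (for singletons
#' \eqn{Q = d^2/2}), reconciling the quadratic form of \eqn{Q} with the
#' stated \eqn{K = 2^{-1/2}} prefactor; \eqn{Q} itself is kept in merge
#' records (column \code{rawQ}) for audit. The convention is a strictly
#' increasing transform, so merge order and penalties are unaffected by
#' the choice. Empty clusters give 0.
#'
#' @inheritParams setDistanceUPGMA
#' @return Non-negative numeric set distance (\eqn{\sqrt{Q}} scale).
#' @export
setDistanceWard <- function(c1, c2, d) {
    v <- .distValues(d)
    i1 <- .resolveMembers(c1, rownames(v))
    i2 <- .resolveMembers(c2, rownames(v))
    if (!length(i1) || !length(i2)) return(0)
    if (length(intersect(i1, i2)))
        stop("clusters must be disjoint")
    n1 <- length(i1); n2 <- length(i2)
    sq <- v^2
    D1 <- sum(sq[i1, i1]) / 2
    D2 <- sum(sq[i2, i2]) / 2
    D12 <- sum(sq[i1, i2])
    Q <- D12 / (n1 + n2) - n2 * D1 / (n1 * (n1 + n2)) -
        n1 * D2 / (n2 * (n1 + n2))
    sqrt(max(Q, 0))
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Runs the agglomeration: starting from singleton clusters
#' \eqn{C_\tau = \{\tau\}}, at each step the pair of uncombined clusters
#' with minimum set distance is merged into a new cluster, until one
#' cluster remains, giving the historical list
#' \eqn{C_1, \ldots, C_{2N_s-1}}. Merge heights are the merging set
#' distances. Ties on the minimum are broken by the lexicographically
#' smallest historical index pair \eqn{(\tau', \tau'')}, making the
#' algorithm total and deterministic.
#'
#' Internally the Lance-Williams recurrences are used (Ward and the
#' centroid methods on squared distances); for \code{"ward"} and
#' \code{"upgma"} this is exactly equivalent to re-evaluating
#' [setDistanceWard()] / [setDistanceUPGMA()] from the base matrix at
#' every step, a property the test suite verifies against the direct
#' formulas.
#'
#' @param d A [TrackDistanceMatrix-class] or symmetric non-negative
#'   matrix with zero diagonal and unique dimnames.
#' @param method One of \code{"ward"}, \code{"upgma"}, \code{"wpgma"},
#'   \code{"upgmc"}, \code{"wpgmc"}.
#' @return A [PeakDendrogram-class].
#' @examples
#' m <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' mergeTable(agglomerate(m, "upgma"))
#' @export
agglomerate <- function(d, method = c("ward", "upgma", "wpgma",
                                      "upgmc", "wpgmc")) {
    method <- match.arg(method)
    v <- .distValues(d)
    n <- nrow(v)
    if (n < 2L) stop("at least two samples are required")
    ids <- rownames(v)
    if (is.null(ids) || anyDuplicated(ids))
        stop("distance matrix must have unique dimnames")
    if (any(abs(v - t(v)) > 1e-9) || any(v < 0) ||
        any(abs(diag(v)) > 1e-12))
        stop("distance matrix must be symmetric, non-negative, with zero diagonal")

    squared <- method %in% c("ward", "upgmc", "wpgmc")
    total <- 2L * n - 1L
    ## working inter-cluster values, indexed by historical cluster id
    W <- matrix(NA_real_, total, total)
    W[seq_len(n), seq_len(n)] <- if (squared) v^2 else v
    sizes <- c(rep(1L, n), rep(NA_integer_, n - 1L))
    clusters <- vector("list", total)
    clusters[seq_len(n)] <- as.list(seq_len(n))
    active <- seq_len(n)
    merges <- data.frame(step = seq_len(n - 1L), tau1 = NA_integer_,
                         tau2 = NA_integer_, height = NA_real_,
                         rawQ = NA_real_)

    for (t in seq_len(n - 1L)) {
        ## minimum over active pairs; first (lexicographic) pair wins ties
        best <- Inf; bi <- NA_integer_; bj <- NA_integer_
        act <- sort(active)
        for (ii in seq_len(length(act) - 1L)) {
            i <- act[ii]
            wrow <- W[i, act[(ii + 1L):length(act)]]
            jbest <- which.min(wrow)  # first minimum
            if (wrow[jbest] < best) {
                best <- wrow[jbest]; bi <- i
                bj <- act[ii + jbest]
            }
        }
        newId <- n + t
        na <- sizes[bi]; nb <- sizes[bj]
        height <- switch(method,
            ward = sqrt(max(best, 0) / 2),
            upgma = best,
            wpgma = best,
            upgmc = sqrt(max(best, 0)),
            wpgmc = sqrt(max(best, 0)))
        merges$tau1[t] <- bi; merges$tau2[t] <- bj
        merges$height[t] <- height
        if (method == "ward") merges$rawQ[t] <- best / 2
        clusters[[newId]] <- c(clusters[[bi]], clusters[[bj]])
        sizes[newId] <- na + nb
        active <- c(setdiff(active, c(bi, bj)), newId)
        for (k in setdiff(active, newId)) {
            nk <- sizes[k]
            wak <- W[bi, k]; wbk <- W[bj, k]; wab <- W[bi, bj]
            W[newId, k] <- W[k, newId] <- switch(method,
                ward = ((na + nk) * wak + (nb + nk) * wbk - nk * wab) /
                    (na + nb + nk),
                upgma = (na * wak + nb * wbk) / (na + nb),
                wpgma = (wak + wbk) / 2,
                upgmc = (na * wak + nb * wbk) / (na + nb) -
                    na * nb * wab / (na + nb)^2,
                wpgmc = (wak + wbk) / 2 - wab / 4)
        }
    }
    new("PeakDendrogram", labels = ids, merges = merges,
        clusters = clusters, method = method)
}

#' Rebuild a dendrogram from an explicit merge table
#'
#' Constructs a [PeakDendrogram-class] directly from merge records —
#' e.g. read back from a merge-table TSV — for penalty-only workflows
#' where the distance matrix is not needed.
#'
#' @param labels Character vector of the \eqn{N_s} sample labels (leaf
#'   index order).
#' @param merges data.frame with columns \code{tau1}, \code{tau2} (and
#'   optionally \code{height}, \code{rawQ}); row \eqn{t} creates cluster
#'   \eqn{N_s + t} from the two historical indices.
#' @param method Method label recorded on the result.
#' @return A [PeakDendrogram-class].
#' @export
dendrogramFromMerges <- function(labels, merges, method = "imported") {
    n <- length(labels)
    merges <- as.data.frame(merges)
    if (!all(c("tau1", "tau2") %in% colnames(merges)))
        stop("merges must have columns tau1 and tau2")
    if (is.null(merges$height)) merges$height <- seq_len(nrow(merges))
    if (is.null(merges$rawQ)) merges$rawQ <- NA_real_
    merges$step <- seq_len(nrow(merges))
    merges <- merges[, c("step", "tau1", "tau2", "height", "rawQ")]
    clusters <- vector("list", 2L * n - 1L)
    clusters[seq_len(n)] <- as.list(seq_len(n))
    for (t in seq_len(nrow(merges)))
        clusters[[n + t]] <- c(clusters[[merges$tau1[t]]],
                               clusters[[merges$tau2[t]]])
    new("PeakDendrogram", labels = labels, merges = merges,
        clusters = clusters, method = method)
}

#' Node coordinates for drawing a dendrogram
#'
#' Computes the drawing coordinates: leaf \eqn{\tau} sits at
#' \eqn{(a_\tau, 0)} where \eqn{a_\tau} is its position in the root
#' cluster's member ordering, and the node created at step \eqn{t} sits
#' at \eqn{((a_{\tau'} + a_{\tau''})/2, \; h_t)} — the midpoint of its
#' two children, at its merge height. For Ward and UPGMA every mother
#' node is at least as high as its children.
#'
#' @param x A [PeakDendrogram-class].
#' @return data.frame with columns \code{node} (historical index),
#'   \code{x}, \code{y}, \code{label} (leaf label or \code{NA}).
#' @export
nodeCoordinates <- function(x) {
    stopifnot(is(x, "PeakDendrogram"))
    n <- length(x@labels)
    total <- 2L * n - 1L
    rootOrder <- x@clusters[[total]]
    xs <- numeric(total); ys <- numeric(total)
    xs[rootOrder] <- seq_len(n)          # a_tau for leaves
    for (t in seq_len(n - 1L)) {
        t1 <- x@merges$tau1[t]; t2 <- x@merges$tau2[t]
        xs[n + t] <- (xs[t1] + xs[t2]) / 2
        ys[n + t] <- x@merges$height[t]
    }
    data.frame(node = seq_len(total), x = xs, y = ys,
               label = c(x@labels, rep(NA_character_, n - 1L)))
}

#' Write / read a flat merge table
#'
#' Serializes the merge records as TSV (columns \code{step},
#' \code{tau1}, \code{tau2}, \code{height}, \code{rawQ});
#' \code{readMergeTable} rebuilds the dendrogram given the leaf labels.
#'
#' @param x A [PeakDendrogram-class].
#' @param path File path.
#' @return \code{writeMergeTable}: invisibly \code{path};
#'   \code{readMergeTable}: a [PeakDendrogram-class].
#' @export
writeMergeTable <- function(x, path) {
    utils::write.table(x@merges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeMergeTable
#' @param labels Leaf labels for the rebuilt dendrogram.
#' @export
readMergeTable <- function(path, labels) {
    merges <- utils::read.table(path, sep = "\t", header = TRUE)
    dendrogramFromMerges(labels, merges)
}

#' Convert to a base-R hclust object
#'
#' Maps the historical merge records to the \code{\link[stats]{hclust}}
#' encoding (negative singleton indices, positive merge-step indices) so
#' standard plotting and cutting tools apply. The leaf order is the root
#' cluster's member ordering.
#'
#' @param x A [PeakDendrogram-class].
#' @param ... Ignored.
#' @return An object of class \code{hclust}.
#' @exportS3Method stats::as.hclust
as.hclust.PeakDendrogram <- function(x, ...) {
    n <- length(x@labels)
    enc <- function(tau) ifelse(tau <= n, -tau, tau - n)
    structure(list(
        merge = cbind(enc(x@merges$tau1), enc(x@merges$tau2)),
        height = x@merges$height,
        order = x@clusters[[2L * n - 1L]],
        labels = x@labels,
        method = x@method,
        call = match.call(),
        dist.method = "hamming"), class = "hclust")
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are derived from merge heights through the standard
#' ultrametric conversion of \code{hclust} trees.
#'
#' @param x A [PeakDendrogram-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
exportNewick <- function(x, path) {
    phy <- ape::as.phylo(stats::as.hclust(x))
    ape::write.tree(phy, file = path)
    invisible(path)
}

## ---- accessors ----

#' @describeIn PeakDendrogram-class Offspring set of node \code{tau}.
#' @param tau Historical cluster index.
#' @export
setMethod("offspring", "PeakDendrogram", function(x, tau) {
    total <- 2L * length(x@labels) - 1L
    if (!is.numeric(tau) || length(tau) != 1L || tau < 1 || tau > total)
        stop("tau must be a single index in 1..", total)
    x@labels[x@clusters[[as.integer(tau)]]]
})

#' @describeIn PeakDendrogram-class Merge records.
#' @param x A [PeakDendrogram-class].
#' @export
setMethod("mergeTable", "PeakDendrogram", function(x) x@merges)

#' @describeIn PeakDendrogram-class Linkage label.
#' @export
setMethod("linkageMethod", "PeakDendrogram", function(x) x@method)

#' @describeIn PeakDendrogram-class Sample labels in leaf-index order.
#' @export
setMethod("sampleIds", "PeakDendrogram", function(x) x@labels)

setMethod("show", "PeakDendrogram", function(object) {
    n <- length(object@labels)
    cat("PeakDendrogram (", object@method, ") over ", n, " samples, ",
        n - 1L, " merges\n", sep = "")
})
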