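# Shared fixtures and independent oracles. Oracles deliberately use the
# naive per-position representation the package avoids, so they share no
# code path with the implementation they check.

toyLayout <- function(sizes = c(chr1 = 50000L)) {
  genomeLayout(names(sizes), sizes)
}

# Build a BinaryTrack directly from interval coordinates.
makeTrack <- function(layout, chrom, start, end, mCut = Inf) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               negLog10P = rep(5, length(start)))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
  GenomeInfoDb::seqinfo(gr) <- layout
  binarize(rankPeaks(gr), mCut = mCut)
}

# Random track: n peaks of random widths, possibly overlapping.
randomTrack <- function(layout, n, maxWidth = 400L) {
  lens <- GenomeInfoDb::seqlengths(layout)
  ch <- sample(names(lens), n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  st <- vapply(seq_len(n), function(i)
    sample.int(lens[ch[i]] - w[i], 1L), integer(1))
  makeTrack(layout, ch, st, st + w - 1L)
}

# Oracle: explicit 0/1 vector of a track over the whole (toy) genome.
trackToVector <- function(track) {
  gr <- peakRanges(track)
  lens <- GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(gr))
  offs <- c(0, cumsum(as.numeric(lens)))[seq_along(lens)]
  names(offs) <- names(lens)
  v <- integer(sum(lens))
  for (i in seq_along(gr)) {
    o <- offs[as.character(GenomeInfoDb::seqnames(gr)[i])]
    v[(o + GenomicRanges::start(gr)[i]):(o + GenomicRanges::end(gr)[i])] <- 1L
  }
  v
}

# Oracle: Hamming distance as an explicit XOR count.
hammingOracle <- function(a, b) {
  sum(trackToVector(a) != trackToVector(b))
}

# Oracle: agglomeration by direct evaluation of the set-distance formulas
# from the base matrix at every step (no Lance-Williams recurrence).
# Returns merge records in the same layout as mergeTable().
directAgglomerate <- function(v, method = c("ward", "upgma")) {
  method <- match.arg(method)
  setDist <- if (method == "ward") setDistanceWard else setDistanceUPGMA
  n <- nrow(v)
  clusters <- as.list(seq_len(n))
  active <- seq_len(n)
  out <- data.frame(step = seq_len(n - 1L), tau1 = NA_integer_,
                    tau2 = NA_integer_, height = NA_real_)
  for (t in seq_len(n - 1L)) {
    best <- Inf; bi <- NA; bj <- NA
    act <- sort(active)
    for (ii in seq_len(length(act) - 1L))
      for (jj in (ii + 1L):length(act)) {
        h <- setDist(clusters[[act[ii]]], clusters[[act[jj]]], v)
        if (h < best) { best <- h; bi <- act[ii]; bj <- act[jj] }
      }
    out$tau1[t] <- bi; out$tau2[t] <- bj; out$height[t] <- best
    clusters[[n + t]] <- c(clusters[[bi]], clusters[[bj]])
    active <- c(setdiff(active, c(bi, bj)), n + t)
  }
  out
}

# Random symmetric distance matrix with zero diagonal.
randomDistMatrix <- function(n, integerValued = FALSE) {
  v <- matrix(0, n, n)
  up <- upper.tri(v)
  vals <- if (integerValued) sample.int(100L, sum(up), replace = TRUE)
          else stats::runif(sum(up), 0.5, 100)
  v[up] <- vals
  v <- v + t(v)
  dimnames(v) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  v
}

# Small planted cohort spec used where full defaults would be slow.
smallCohortSpec <- function(seed = 42L, ...) {
  cohortSpec(samplesPerType = 2L, kInfo = 60L, kNoise = 30L,
             seed = seed, ...)
}

# The worked 6-leaf example: three HSC samples whose minimal covering
# cluster also contains MPP (node 10), plus a Mono pair.
hscExampleDendrogram <- function() {
  dendrogramFromMerges(
    c("HSC1", "HSC2", "HSC3", "MPP", "Mono1", "Mono2"),
    data.frame(tau1 = c(1, 4, 5, 3, 9), tau2 = c(2, 7, 6, 8, 10),
               height = 1:5))
}

hscExampleLabels <- c(HSC1 = "HSC", HSC2 = "HSC", HSC3 = "HSC",
                      MPP = "MPP", Mono1 = "Mono", Mono2 = "Mono")
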