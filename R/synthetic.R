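#' Specification of a synthetic labeled cohort
#'
#' Describes a planted-structure cohort on a toy genome: each cell type
#' has an archetype of \code{kInfo} non-overlapping "informative" peaks
#' (some shared across types), and each sample is a positionally
#' jittered copy of its type's archetype plus \code{kNoise}
#' sample-specific noise peaks at random positions. Informative peaks
#' receive \eqn{-\log_{10} p} scores strictly above the noise scores, so
#' truncating at \eqn{M_{cut} = kInfo} removes exactly the noise — the
#' construction that makes a zero global penalty provable.
#'
#' @param chromLengths Named vector of chromosome lengths (default two
#'   chromosomes of 150 kb, sized so the default archetypes fit without
#'   overlap).
#' @param types Character vector of cell-type labels.
#' @param samplesPerType Replicates per type.
#' @param kInfo Archetype (informative) peaks per type.
#' @param kNoise Noise peaks per sample.
#' @param sharedFraction Fraction of each archetype shared by all types.
#' @param slotSpacing Spacing (bp) of the non-overlapping archetype peak
#'   slots.
#' @param infoWidth,noiseWidth Length-2 vectors \code{c(mean, sd)} of the
#'   (clamped normal) peak-width distributions.
#' @param infoScores,noiseScores Length-2 ranges of the uniform
#'   \eqn{-\log_{10} p} score draws; the informative minimum must exceed
#'   the noise maximum (the score margin).
#' @param jitterSD SD (bp) of the per-sample integer positional jitter.
#' @param pG Nominal calling threshold recorded on the ranked sets; all
#'   scores must satisfy \eqn{-\log_{10} p \ge -\log_{10} p_G}.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class \code{"cohortSpec"}.
#' @seealso [simulateCohort()]
#' @export
cohortSpec <- function(chromLengths = c(chr1 = 150000L, chr2 = 150000L),
                       types = c("TypeA", "TypeB", "TypeC"),
                       samplesPerType = 4L,
                       kInfo = 300L, kNoise = 200L,
                       sharedFraction = 1 / 3,
                       slotSpacing = 280L,
                       infoWidth = c(150, 30), noiseWidth = c(80, 20),
                       infoScores = c(20, 100), noiseScores = c(2, 10),
                       jitterSD = 10, pG = 1e-2, seed = 20201L) {
    if (min(infoScores) <= max(noiseScores))
        stop("informative scores must strictly exceed noise scores ",
             "(positive margin required)")
    if (min(noiseScores) < -log10(pG) - 1e-9)
        stop("all scores must be consistent with the pG threshold")
    spec <- list(chromLengths = chromLengths, types = types,
                 samplesPerType = as.integer(samplesPerType),
                 kInfo = as.integer(kInfo), kNoise = as.integer(kNoise),
                 sharedFraction = sharedFraction,
                 slotSpacing = as.integer(slotSpacing),
                 infoWidth = infoWidth, noiseWidth = noiseWidth,
                 infoScores = infoScores, noiseScores = noiseScores,
                 jitterSD = jitterSD, pG = pG, seed = as.integer(seed))
    class(spec) <- "cohortSpec"
    spec
}

## Internal: draw clamped-normal integer widths.
.drawWidths <- function(n, meanSD, lo = 40L, hi = NULL) {
    w <- as.integer(round(stats::rnorm(n, meanSD[1], meanSD[2])))
    if (is.null(hi)) hi <- as.integer(meanSD[1] + 4 * meanSD[2])
    pmin(pmax(w, lo), hi)
}

## Internal: peaks from (chrom, center, width), clamped to chromosome.
.peaksFromCenters <- function(chrom, center, width, lens) {
    start <- center - width %/% 2L
    end <- start + width - 1L
    L <- lens[chrom]
    start <- pmax(start, 1L); end <- pmin(end, L)
    GRanges(chrom, IRanges::IRanges(start, end))
}

## Internal: one sample drawn from an archetype under a spec (uses the
## current RNG stream).
.sampleFromArchetype <- function(arch, spec, layout) {
    lens <- GenomeInfoDb::seqlengths(layout)
    k <- length(arch)
    shift <- as.integer(round(stats::rnorm(k, 0, spec$jitterSD)))
    start <- pmax(GenomicRanges::start(arch) + shift, 1L)
    end <- GenomicRanges::end(arch) + shift
    chrom <- as.character(GenomeInfoDb::seqnames(arch))
    end <- pmin(end, lens[chrom])
    start <- pmin(start, end)
    info <- GRanges(chrom, IRanges::IRanges(start, end))
    mcols(info)$negLog10P <- stats::runif(k, spec$infoScores[1],
                                          spec$infoScores[2])
    kn <- spec$kNoise
    if (kn > 0L) {
        nchrom <- sample(names(lens), kn, replace = TRUE,
                         prob = lens / sum(lens))
        ncenter <- as.integer(floor(stats::runif(kn, 1, lens[nchrom] + 1)))
        noise <- .peaksFromCenters(nchrom, ncenter,
                                   .drawWidths(kn, spec$noiseWidth), lens)
        mcols(noise)$negLog10P <- stats::runif(kn, spec$noiseScores[1],
                                               spec$noiseScores[2])
        info <- c(info, noise)
    }
    rankPeaks(.withLayout(info, layout), pG = spec$pG)
}

#' Simulate a labeled cohort with planted type structure
#'
#' Generates type archetypes on non-overlapping peak slots (a shared
#' block common to all types plus type-specific blocks), then draws
#' every sample as a jittered archetype copy with high scores plus
#' uniform noise peaks with low scores. Deterministic given
#' \code{spec$seed}.
#'
#' @param spec A [cohortSpec()].
#' @return List with elements \code{peaks} (named list of
#'   [RankedPeakSet-class]), \code{labels} (named character vector of
#'   types), \code{layout} ([GenomeInfoDb::Seqinfo]),
#'   \code{archetypes} (named list of [GenomicRanges::GRanges]) and
#'   \code{spec}.
#' @examples
#' co <- simulateCohort(cohortSpec(samplesPerType = 2, kInfo = 50,
#'                                 kNoise = 20))
#' names(co$peaks)
#' @export
simulateCohort <- function(spec) {
    stopifnot(inherits(spec, "cohortSpec"))
    layout <- genomeLayout(names(spec$chromLengths), spec$chromLengths)
    lens <- GenomeInfoDb::seqlengths(layout)
    withSeed(spec$seed, {
        ## non-overlapping slots for archetype peaks
        margin <- as.integer(spec$infoWidth[1] + 4 * spec$infoWidth[2])
        slots <- do.call(rbind, lapply(names(lens), function(ch) {
            centers <- seq.int(margin, lens[ch] - margin,
                               by = spec$slotSpacing)
            data.frame(chrom = ch, center = as.integer(centers))
        }))
        nTypes <- length(spec$types)
        nCommon <- round(spec$sharedFraction * spec$kInfo)
        nSpec <- spec$kInfo - nCommon
        needed <- nCommon + nTypes * nSpec
        if (needed > nrow(slots))
            stop("generation error: ", needed, " archetype slots needed ",
                 "but only ", nrow(slots), " fit the genome")
        pick <- sample.int(nrow(slots), needed)
        common <- pick[seq_len(nCommon)]
        rest <- pick[-seq_len(nCommon)]
        archetypes <- stats::setNames(vector("list", nTypes), spec$types)
        for (ti in seq_len(nTypes)) {
            own <- rest[((ti - 1L) * nSpec + 1L):(ti * nSpec)]
            idx <- c(common, own)
            archetypes[[ti]] <- sort(.withLayout(.peaksFromCenters(
                slots$chrom[idx], slots$center[idx],
                .drawWidths(length(idx), spec$infoWidth,
                            hi = spec$slotSpacing - 20L), lens), layout))
        }
        peaks <- list(); labels <- character()
        for (tp in spec$types)
            for (si in seq_len(spec$samplesPerType)) {
                id <- paste0(tp, "_", si)
                peaks[[id]] <- .sampleFromArchetype(archetypes[[tp]],
                                                    spec, layout)
                labels[id] <- tp
            }
        list(peaks = peaks, labels = labels, layout = layout,
             archetypes = archetypes, spec = spec)
    })
}

#' Simulate a held-out query sample from a cohort's archetype
#'
#' Draws a fresh sample from one type's archetype by the same
#' jitter-plus-noise process used for cohort members, for held-out
#' classification experiments.
#'
#' @param cohort Result of [simulateCohort()].
#' @param type One of the cohort's types.
#' @param seed Integer seed for the query draw.
#' @return A [RankedPeakSet-class].
#' @export
simulateQuery <- function(cohort, type, seed) {
    if (!type %in% names(cohort$archetypes))
        stop("unknown type: ", type)
    withSeed(seed,
        .sampleFromArchetype(cohort$archetypes[[type]], cohort$spec,
                             cohort$layout))
}

#' Write a simulated cohort to disk in standard formats
#'
#' Emits exactly the plain-text formats the real pipeline consumes: one
#' narrowPeak file per sample, a 2-column label TSV and a
#' chromosome-length TSV.
#'
#' @param cohort Result of [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(cohort$peaks))
        writeNarrowPeak(cohort$peaks[[id]],
                        file.path(dir, paste0(id, ".narrowPeak")))
    utils::write.table(
        data.frame(names(cohort$labels), unname(cohort$labels)),
        file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    writeChromLengths(cohort$layout, file.path(dir, "chrom_lengths.tsv"))
    invisible(dir)
}

#' Simulate reads from a peak set
#'
#' Places \code{depthPerPeak} reads per peak (each read overlaps its
#' source peak; starts are uniform over the overlap-compatible range, so
#' expected pileup is flat across the peak) and adds
#' Poisson background reads uniformly over the genome, producing input
#' for [toyPeakCaller()] and the downsampling robustness analysis.
#'
#' @param ranked A [RankedPeakSet-class].
#' @param depthPerPeak Reads per peak.
#' @param backgroundRate Expected background reads per bp of genome.
#' @param seed Integer seed.
#' @param readLength Read length in bp (default 50).
#' @return A [GenomicRanges::GRanges] of reads.
#' @export
simulateReads <- function(ranked, depthPerPeak, backgroundRate, seed,
                          readLength = 50L) {
    stopifnot(is(ranked, "RankedPeakSet"))
    gr <- peakRanges(ranked)
    layout <- GenomeInfoDb::seqinfo(gr)
    lens <- GenomeInfoDb::seqlengths(layout)
    withSeed(seed, {
        reads <- GRanges(seqinfo = layout)
        if (depthPerPeak > 0L && length(gr)) {
            idx <- rep(seq_along(gr), each = depthPerPeak)
            ## read start anywhere that still overlaps the peak, so the
            ## expected pileup is uniform across the whole peak interval
            lo <- pmax(GenomicRanges::start(gr)[idx] - readLength + 1L, 1L)
            hi <- GenomicRanges::end(gr)[idx]
            st <- as.integer(floor(stats::runif(length(idx), lo, hi + 1)))
            ch <- as.character(GenomeInfoDb::seqnames(gr))[idx]
            en <- pmin(st + readLength - 1L, lens[ch])
            reads <- GRanges(ch, IRanges::IRanges(st, en), seqinfo = layout)
        }
        nBg <- if (backgroundRate > 0)
            stats::rpois(1, backgroundRate * sum(as.numeric(lens))) else 0L
        if (nBg > 0L) {
            ch <- sample(names(lens), nBg, replace = TRUE,
                         prob = lens / sum(lens))
            st <- as.integer(floor(stats::runif(nBg, 1,
                                                pmax(1, lens[ch] - readLength + 1) + 1)))
            en <- pmin(st + readLength - 1L, lens[ch])
            reads <- c(reads, GRanges(ch, IRanges::IRanges(st, en),
                                      seqinfo = layout))
        }
        reads
    })
}

#' Toy peak caller over a read pileup
#'
#' A hermetic stand-in honoring the external-caller output contract:
#' maximal runs of positions whose read pileup reaches
#' \code{coverageThreshold} become peaks, scored by a monotone function
#' of the run's maximum pileup, floored at \eqn{-\log_{10} p_G} so every
#' implied p-value satisfies \eqn{p \le p_G}. Fully deterministic. It
#' makes no claim of fidelity to a model-based caller; it exists so the
#' wrapper and robustness code paths are testable without external
#' binaries.
#'
#' @param reads A [GenomicRanges::GRanges] of reads with complete
#'   seqlengths.
#' @param coverageThreshold Minimum pileup for a position to be inside a
#'   peak.
#' @param pG Calling threshold determining the score floor.
#' @return A [GenomicRanges::GRanges] of peaks with \code{negLog10P}.
#' @export
toyPeakCaller <- function(reads, coverageThreshold = 10L, pG = 1e-2) {
    cov <- GenomicRanges::coverage(reads)
    out <- GRanges(seqinfo = GenomeInfoDb::seqinfo(reads))
    mcols(out)$negLog10P <- numeric(0)
    for (ch in names(cov)) {
        sl <- IRanges::slice(cov[[ch]], lower = coverageThreshold)
        if (!length(sl)) next
        maxs <- IRanges::viewMaxs(sl)
        gr <- GRanges(ch, IRanges::IRanges(IRanges::start(sl),
                                           IRanges::end(sl)),
                      seqinfo = GenomeInfoDb::seqinfo(reads))
        mcols(gr)$negLog10P <- -log10(pG) +
            (maxs - coverageThreshold)
        out <- c(out, gr)
    }
    out
}
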