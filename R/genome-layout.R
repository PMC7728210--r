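#' Construct a genome layout (chromosome names and lengths)
#'
#' The genome layout is the ordered set of chromosome labels
#' \eqn{\mathbb{X}} together with the length \eqn{L_\gamma} of each
#' chromosome, represented as a [GenomeInfoDb::Seqinfo] — the standard
#' Bioconductor container all ranges in the package are validated against.
#'
#' @param chromosomes Character vector of unique chromosome labels.
#' @param lengths Integer-like vector of chromosome lengths (>= 1 bp),
#'   parallel to \code{chromosomes}.
#' @return A [GenomeInfoDb::Seqinfo].
#' @examples
#' genomeLayout(c("chr1", "chr2"), c(150000, 150000))
#' @export
genomeLayout <- function(chromosomes, lengths) {
    chromosomes <- as.character(chromosomes)
    if (anyDuplicated(chromosomes))
        stop("chromosome labels must be unique")
    lengths <- as.integer(lengths)
    if (length(lengths) != length(chromosomes) || anyNA(lengths) ||
        any(lengths < 1L))
        stop("every chromosome length must be a positive integer")
    GenomeInfoDb::Seqinfo(seqnames = chromosomes, seqlengths = lengths)
}

#' Read a chromosome-length table
#'
#' Reads a 2-column tab-separated table (chromosome label, length in bp),
#' the usual \code{chrom.sizes} format, into a genome layout.
#'
#' @param path Path to the TSV file (no header).
#' @return A [GenomeInfoDb::Seqinfo].
#' @seealso [genomeLayout()]
#' @export
readChromLengths <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "integer"))
    genomeLayout(tab$chrom, tab$length)
}

#' Write a chromosome-length table
#'
#' @param layout A [GenomeInfoDb::Seqinfo].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeChromLengths <- function(layout, path) {
    utils::write.table(
        data.frame(GenomeInfoDb::seqnames(layout),
                   GenomeInfoDb::seqlengths(layout)),
        path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    invisible(path)
}

## Internal: assert that a GRanges lies within its layout (1-based
## inclusive, 1 <= start <= end <= L_gamma) and that all seqnames are known.
.checkWithinLayout <- function(gr, layout, what = "range") {
    known <- GenomeInfoDb::seqnames(layout)
    sn <- as.character(GenomeInfoDb::seqnames(gr))
    bad <- !sn %in% known
    if (any(bad))
        stop("chromosome(s) absent from layout: ",
             paste(unique(sn[bad]), collapse = ", "))
    lens <- GenomeInfoDb::seqlengths(layout)[sn]
    out <- GenomicRanges::start(gr) < 1L | GenomicRanges::end(gr) > lens
    if (any(out))
        stop(sum(out), " ", what, "(s) fall outside the chromosome bounds ",
             "(first at index ", which(out)[1], ")")
    invisible(TRUE)
}

## Internal: impose a layout's seqinfo on a GRanges (after bounds check).
.withLayout <- function(gr, layout) {
    .checkWithinLayout(gr, layout)
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
    gr
}

## Internal: check two GRanges share one layout.
.sameLayout <- function(a, b) {
    ia <- GenomeInfoDb::seqinfo(a); ib <- GenomeInfoDb::seqinfo(b)
    identical(GenomeInfoDb::seqnames(ia), GenomeInfoDb::seqnames(ib)) &&
        identical(GenomeInfoDb::seqlengths(ia), GenomeInfoDb::seqlengths(ib))
}
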