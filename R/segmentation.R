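#' Default ChromHMM core-15 mnemonic aliases
#'
#' Maps the Roadmap core 15-state mnemonics used in segmentation files
#' (e.g. \code{1_TssA}) to the human-readable labels used in annotation
#' profiles (e.g. \code{ActiveTSS}). Pass a modified copy to
#' [readChromHMM()] to override.
#'
#' @return Named character vector: names are file mnemonics, values are
#'   display labels.
#' @export
chromhmmAliases <- function() {
    c("1_TssA"      = "ActiveTSS",
      "2_TssAFlnk"  = "FlankingActiveTSS",
      "3_TxFlnk"    = "TranscrAtGene5and3",
      "4_Tx"        = "StrongTranscription",
      "5_TxWk"      = "WeakTranscription",
      "6_EnhG"      = "GenicEnhancers",
      "7_Enh"       = "Enhancers",
      "8_ZNF/Rpts"  = "ZNFgenesRepeats",
      "9_Het"       = "Heterochromatin",
      "10_TssBiv"   = "BivalentPoisedTSS",
      "11_BivFlnk"  = "FlankingBivalent",
      "12_EnhBiv"   = "BivalentEnhancer",
      "13_ReprPC"   = "RepressedPolyComb",
      "14_ReprPCWk" = "WeakRepressedPolyComb",
      "15_Quies"    = "Quiescent_Low")
}

#' Read a ChromHMM segmentation BED file
#'
#' Imports a 4-column segmentation BED (chrom, start, end, state),
#' converts 0-based half-open coordinates to 1-based inclusive, and
#' translates state mnemonics through an alias map (labels without an
#' alias are kept verbatim). Adjacent same-state intervals are stored as
#' given — no auto-merging — but overlapping intervals within one state
#' are a validation error.
#'
#' @param path Path to the segmentation BED.
#' @param layout Genome layout the segmentation must lie within.
#' @param aliases Named character vector translating file mnemonics to
#'   display labels; defaults to [chromhmmAliases()].
#' @return A [GenomicRanges::GRanges] with a \code{state} metadata column.
#' @export
readChromHMM <- function(path, layout, aliases = chromhmmAliases()) {
    if (!file.exists(path)) stop("file not found: ", path)
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) stop("segmentation parse error in '",
                                            path, "': ", conditionMessage(e),
                                            call. = FALSE))
    if (is.null(gr$name) || anyNA(gr$name))
        stop("segmentation parse error in '", path,
             "': every interval needs a state label in column 4")
    state <- as.character(gr$name)
    hit <- state %in% names(aliases)
    state[hit] <- aliases[state[hit]]
    out <- GRanges(GenomeInfoDb::seqnames(gr), IRanges::ranges(gr),
                   state = state)
    out <- .withLayout(out, layout)
    .checkSegmentation(out)
    out
}

## Internal: within one state, intervals must not overlap.
.checkSegmentation <- function(seg) {
    for (st in unique(seg$state)) {
        sub <- seg[seg$state == st]
        if (!GenomicRanges::isDisjoint(sub))
            stop("overlapping intervals within state '", st, "'")
    }
    invisible(TRUE)
}
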