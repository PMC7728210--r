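#' Build the MACS2 callpeak command line
#'
#' Constructs (without running) the exact \code{macs2 callpeak} invocation
#' the pipeline uses: \code{--nomodel --nolambda --keep-dup all -p pG}.
#' The p-value threshold is formatted without scientific-notation
#' surprises so that, e.g., \eqn{p_G = 10^{-2}} yields \code{-p 0.01}.
#'
#' @param readsFile Path to the analysis-ready reads file (BED/tagAlign;
#'   duplicates removed and MQ-filtered upstream).
#' @param pG Peak-calling significance threshold in (0, 1).
#' @param workdir Output directory passed to \code{--outdir}.
#' @param name Sample name passed to \code{-n} (defaults to the reads
#'   file base name).
#' @return Character vector: the executable followed by its arguments.
#' @examples
#' macs2Command("s1.bed", 1e-2, "out")
#' @export
macs2Command <- function(readsFile, pG, workdir, name = NULL) {
    if (!is.numeric(pG) || length(pG) != 1L || pG <= 0 || pG >= 1)
        stop("pG must be a single value in (0, 1)")
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(readsFile))
    c("macs2", "callpeak",
      "-t", readsFile,
      "-n", name,
      "--outdir", workdir,
      "--nomodel", "--nolambda", "--keep-dup", "all",
      "-p", format(pG, scientific = FALSE, trim = TRUE))
}

#' Call peaks with the external MACS2 caller
#'
#' Runs MACS2 \code{callpeak} on a reads file with the fixed flag set
#' \code{--nomodel --nolambda --keep-dup all -p pG} and parses the
#' resulting narrowPeak file. Every returned peak satisfies
#' \eqn{p_k \le p_G} by construction of the caller. Note the contract
#' makes no nesting assumption across \eqn{p_G} values: a single peak
#' called at \eqn{p_G = 10^{-2}} may split into two narrower peaks at
#' \eqn{p_G = 10^{-4}}.
#'
#' @inheritParams macs2Command
#' @param layout Genome layout used to validate the parsed peaks.
#' @return A [GenomicRanges::GRanges] of peaks with \code{negLog10P}, in
#'   caller output order.
#' @seealso [toyPeakCaller()] for a hermetic stand-in with the same
#'   output contract, used in tests and robustness simulations.
#' @export
callPeaksMACS2 <- function(readsFile, pG, workdir, layout, name = NULL) {
    if (Sys.which("macs2") == "")
        stop("external peak caller 'macs2' not found on PATH")
    if (!file.exists(readsFile)) stop("reads file not found: ", readsFile)
    dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
    cmd <- macs2Command(readsFile, pG, workdir, name)
    log <- suppressWarnings(
        system2(cmd[1], cmd[-1], stdout = TRUE, stderr = TRUE))
    status <- attr(log, "status")
    if (!is.null(status) && status != 0L)
        stop("macs2 callpeak exited with status ", status, ":\n",
             paste(utils::tail(log, 20), collapse = "\n"))
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(readsFile))
    np <- file.path(workdir, paste0(name, "_peaks.narrowPeak"))
    if (!file.exists(np))
        stop("macs2 produced no narrowPeak output at ", np)
    readNarrowPeak(np, layout)
}
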