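#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{code} with the global RNG seeded to \code{seed} and
#' restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb surrounding randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed %% 2147483647))
    code
}
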