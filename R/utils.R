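#' @importFrom stats rnorm runif rlnorm qnorm pnorm pt sd cor quantile dgamma
#'   aggregate convolve
#' @importFrom methods new validObject is slot
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL leaves the stream alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stage-specific child seed from a master seed
#'
#' Hashes the master seed together with a stage name into a reproducible
#' 31-bit integer, so each pipeline stage draws from an independent,
#' individually re-runnable stream.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
childSeed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- as.double(master) %% 2147483647
  for (cc in utf8ToInt(stage)) h <- (h * 69069 + cc) %% 2147483647
  as.integer(h %% 2147483645L + 1L)
}

stopStructural <- function(msg) {
  stop(errorCondition(msg, class = c("seqBOLD_structural_error", "error")))
}

stopFeasibility <- function(msg, constraint) {
  stop(errorCondition(
    sprintf("%s (binding constraint: %s)", msg, constraint),
    class = c("seqBOLD_feasibility_error", "error")))
}
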