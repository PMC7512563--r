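# Explicit RNG streams. Every stochastic routine in the package draws from a
# stream object passed in explicitly; the caller's global .Random.seed is
# saved and restored around each draw, so no function has hidden global
# state. Independent sub-streams (data / folds / GA) are derived from one
# master seed.

#' Create a seeded random stream
#'
#' @param seed integer seed.
#' @return an object of class \code{rng_stream}.
#' @export
rng_stream <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  st <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  e <- new.env(parent = emptyenv())
  e$state <- st
  e$seed <- as.integer(seed)
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression using a stream's RNG state
#'
#' @param rng an \code{rng_stream}.
#' @param expr expression drawing random numbers.
#' @return the value of \code{expr}; the stream state is advanced.
#' @export
with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' Derive an independent sub-stream from a master seed
#'
#' @param seed master integer seed.
#' @param stream small non-negative integer naming the sub-stream.
#' @return an \code{rng_stream}.
#' @export
rng_substream <- function(seed, stream) {
  # distinct affine map per stream, folded into the 32-bit integer range
  rng_stream((as.numeric(seed) * 48271 + 7919 * (stream + 1)) %% 2147483647)
}
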