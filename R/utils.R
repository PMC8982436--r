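#' Derive a reproducible integer seed from components
#'
#' Mixes one or more non-negative integers into a single seed below 2^31,
#' so that independent random streams (per cell, per embryo, per stage) can be
#' derived deterministically from one top-level seed. The mixing is a simple
#' multiplicative congruential fold; collisions are possible in principle but
#' irrelevant at the scales used here.
#'
#' @param ... integer-like components (seed, labels, stage tags, ...).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(...) {
  vals <- as.numeric(unlist(list(...)))
  if (any(!is.finite(vals))) stop("seed components must be finite")
  m <- 2147483647 # 2^31 - 1, prime
  h <- 104729
  for (v in vals) {
    h <- (h * 69069 + (abs(v) %% m) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' library code never clobbers the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# internal: lightweight logging to stderr, silenced via option
eq_log <- function(fmt, ...) {
  if (isTRUE(getOption("embryoquant.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(fmt, ...))
  invisible(NULL)
}
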