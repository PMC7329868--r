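# Internal utilities: reproducible RNG streams, seed derivation, HU clamping.

#' Create an independent random-number stream
#'
#' Wraps an isolated Mersenne-Twister state so that every stochastic operation
#' in the package (phantom sampling, slice selection, augmentation decisions,
#' weight initialisation, training batches) can be made a pure function of an
#' integer seed without disturbing the caller's global RNG state.
#'
#' @param seed Integer seed. Any value is reduced modulo `2^31 - 1`.
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- .save_global_rng()
  set.seed(as.integer(abs(seed) %% 2147483647))
  env$state <- get(".Random.seed", envir = globalenv())
  .restore_global_rng(old)
  class(env) <- "rng_stream"
  env
}

.save_global_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_global_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` under the stream's RNG state, then save the advanced state.
with_stream <- function(rng, expr) {
  stopifnot(inherits(rng, "rng_stream"))
  old <- .save_global_rng()
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    .restore_global_rng(old)
  })
  expr
}

rs_unif <- function(rng, n, min = 0, max = 1) with_stream(rng, stats::runif(n, min, max))
rs_norm <- function(rng, n, mean = 0, sd = 1) with_stream(rng, stats::rnorm(n, mean, sd))
rs_sample <- function(rng, x, size, replace = FALSE) with_stream(rng, sample(x, size, replace = replace))
rs_int <- function(rng, n, lo, hi) {
  stopifnot(hi >= lo)
  with_stream(rng, lo + floor(stats::runif(n) * (hi - lo + 1L)))
}

#' Derive a child seed from a parent seed
#'
#' Deterministic, order-stable fan-out of one master seed into per-stage or
#' per-case seeds. Always returns an integer in `[0, 2^31 - 2]`, safe for
#' [set.seed()].
#'
#' @param seed Parent integer seed.
#' @param k Integer offset (e.g. case index or stage number).
#' @return Integer child seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 1103515245 + as.numeric(k) * 12345 + 7) %% 2147483647)
}

# 12-bit CT storage convention.
HU_MIN <- -1024
HU_MAX <- 3071

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
clamp_hu <- function(x) clamp(x, HU_MIN, HU_MAX)

`%||%` <- function(a, b) if (is.null(a)) b else a
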