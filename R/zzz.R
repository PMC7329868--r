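#' @useDynLib ctseg, .registration = TRUE
NULL

#' Pin the number of BLAS threads
#'
#' Multi-threaded OpenBLAS matrix products are not bitwise reproducible
#' between calls, which would break the package's seed-determinism
#' contracts (identical training trajectories, identical cross-validation
#' grids). The package therefore pins the BLAS to one thread when it loads.
#' Call this to restore a different thread count for throughput-oriented
#' work that does not need bit reproducibility.
#'
#' @param n Thread count (>= 1).
#' @return `TRUE` (invisibly) if a tunable BLAS was found, else `FALSE`.
#' @export
set_blas_threads <- function(n = 1L) {
  invisible(.Call(ctseg_set_blas_threads, as.integer(n)))
}

.onLoad <- function(libname, pkgname) {
  set_blas_threads(1L)
  invisible(NULL)
}
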