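#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic child seed
#'
#' Derives a reproducible 32-bit sub-seed from a base seed and a stream index,
#' so that independent stages of a run consume independent random streams.
#'
#' @param seed integer base seed.
#' @param stream integer stream index (>= 0).
#' @return a single integer suitable for [set.seed()].
#' @export
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Unit-variance Laplace deviates (difference of two exp(1), scaled by 1/sqrt(2))
rlaplace_unit <- function(n) (stats::rexp(n) - stats::rexp(n)) / sqrt(2)
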