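#' Build the multi-shell IVIM acquisition scheme
#'
#' Constructs the diffusion acquisition used throughout the pipeline: 14
#' non-zero b-values from 10 to 3000 s/mm^2 with 3 directions at
#' b = 10, 25, 35, 50, 75, 100 and 200; 10 directions at b = 500 and 750;
#' 20 directions at b = 1000; 5 directions at b = 1500, 2000, 2500 and 3000;
#' plus 2 unweighted (b0) volumes, for a total of 81 weighted directions.
#' Direction vectors are placed deterministically on the unit sphere by a
#' spherical-Fibonacci (golden-angle) construction per shell; IVIM fitting is
#' direction-averaged per shell, so the exact placement only needs to be
#' quasi-uniform and reproducible.
#'
#' @param b_values numeric vector of distinct non-zero b-values (s/mm^2).
#' @param directions_per_b integer vector, directions per b-value (same
#'   length/order as `b_values`).
#' @param n_b0 number of unweighted volumes.
#' @return An object of class `acquisition_scheme`: a list with
#'   `b_values`, `directions_per_b`, `n_b0`, per-volume `bvals` (b0 volumes
#'   first) and `bvecs` (3 x n_volumes; zero columns for b0).
#' @export
#' @examples
#' sch <- build_acquisition_scheme()
#' length(sch$b_values)        # 14 shells
#' sum(sch$directions_per_b)   # 81 weighted directions
build_acquisition_scheme <- function(
    b_values = c(10, 25, 35, 50, 75, 100, 200, 500, 750, 1000,
                 1500, 2000, 2500, 3000),
    directions_per_b = c(3, 3, 3, 3, 3, 3, 3, 10, 10, 20, 5, 5, 5, 5),
    n_b0 = 2) {
  if (length(b_values) != length(directions_per_b))
    stopf("b_values and directions_per_b must have equal length")
  if (any(b_values <= 0)) stopf("non-zero b-values must be positive")
  if (any(directions_per_b < 1)) stopf("each shell needs >= 1 direction")
  ord <- order(b_values)
  b_values <- b_values[ord]
  directions_per_b <- as.integer(directions_per_b[ord])

  bvals <- c(rep(0, n_b0), rep(b_values, directions_per_b))
  bvecs <- matrix(0, nrow = 3, ncol = length(bvals))
  col <- n_b0
  for (i in seq_along(b_values)) {
    nd <- directions_per_b[i]
    # offset the Fibonacci spiral per shell so shells do not share vectors
    bvecs[, col + seq_len(nd)] <- fibonacci_directions(nd, offset = i)
    col <- col + nd
  }
  structure(
    list(b_values = b_values,
         directions_per_b = directions_per_b,
         n_b0 = as.integer(n_b0),
         bvals = bvals,
         bvecs = bvecs),
    class = "acquisition_scheme")
}

#' Quasi-uniform unit direction vectors
#'
#' Spherical-Fibonacci (golden-angle) point set on the unit sphere.
#'
#' @param n number of directions.
#' @param offset integer phase offset rotating the spiral (per-shell variety).
#' @return a 3 x n matrix of unit column vectors.
#' @export
fibonacci_directions <- function(n, offset = 0) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * (i + offset) * (1 - 1 / ((1 + sqrt(5)) / 2))
  r <- sqrt(pmax(0, 1 - z^2))
  v <- rbind(r * cos(phi), r * sin(phi), z)
  sweep(v, 2, sqrt(colSums(v^2)), "/")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("Acquisition scheme: %d b-values (%g-%g s/mm^2), %d weighted directions, %d b0\n",
              length(x$b_values), min(x$b_values), max(x$b_values),
              sum(x$directions_per_b), x$n_b0))
  invisible(x)
}

#' Validate an acquisition scheme
#'
#' Checks the structural invariants: non-negative b-values, unit-norm
#' direction vectors, and volume-count consistency.
#'
#' @param scheme an `acquisition_scheme`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  if (any(scheme$bvals < 0)) stopf("b-values must be >= 0")
  nw <- sum(scheme$directions_per_b)
  if (length(scheme$bvals) != nw + scheme$n_b0)
    stopf("volume count mismatch: %d != %d weighted + %d b0",
          length(scheme$bvals), nw, scheme$n_b0)
  wtd <- scheme$bvals > 0
  norms <- sqrt(colSums(scheme$bvecs[, wtd, drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-9)) stopf("direction vectors must be unit norm")
  invisible(TRUE)
}
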