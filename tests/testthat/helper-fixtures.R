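# small in-code fixtures shared across test files

# minimal two-shell-plus-b0 scheme for cheap structural tests
tiny_scheme <- function() {
  build_acquisition_scheme(b_values = c(100, 1000, 2000, 3000),
                           directions_per_b = c(3, 4, 3, 3), n_b0 = 2)
}

# single-voxel dwi_series with known tri-exponential parameters
tiny_params <- function(dims = c(2, 2, 1), fp = 0.1, ff = 0.2, fs = 0.7,
                        dp = 0.05, df = 3e-3, ds = 7e-4, s0 = 100) {
  mk <- function(v) array(v, dims)
  list(fp = mk(fp), ff = mk(ff), fs = mk(fs), dp = mk(dp), df = mk(df),
       ds = mk(ds), s0 = mk(s0))
}

# uniform-CBF phantom volume
tiny_cbf <- function(dims = c(3, 3, 2), value = 50) array(value, dims)

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * abs(expected)),
              label = sprintf("relative error within %g", tol))
}
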