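# Shared fixtures, memoised so expensive phantoms/coils/calibrations are
# built once per test run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_phantom <- function(n_slices = 2, matrix = 32, seed = 1) {
  memo(sprintf("ph_%d_%d_%d", n_slices, matrix, seed),
       make_brain_phantom(n_slices, matrix, 192, seed = seed))
}

fx_coils <- function(n_slices = 2, matrix = 32, n_coils = 8,
                     tilt = 15, seed = 1) {
  memo(sprintf("co_%d_%d_%d_%g_%d", n_slices, matrix, n_coils, tilt, seed),
       make_coil_sensitivities(fx_phantom(n_slices, matrix), n_coils,
                               tilt, seed = seed))
}

# physics toggles that isolate coil-encoding from distortion terms
ideal_sim <- list(use_offres = FALSE, use_t2s = FALSE,
                  use_fat_shift = FALSE)

# single-band reference reconstruction of one phantom slice under the
# same physics toggles -- the oracle MB separation is compared against
singleband_image <- function(ph, co, s, N, toggles = ideal_sim) {
  sp1 <- protocol_spec(m = 1, n = 1, R_pe = 1, pf = 1, matrix = N)
  mx <- do.call(simulate_mux_acquisition,
                c(list(ph, co, sp1, noise_sigma = 0, slices = s), toggles))
  reconstruct(mx)$slice_images[[as.character(s)]]
}

expect_rel <- function(x, y, tol) {
  expect_lt(abs(x - y) / abs(y), tol)
}
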