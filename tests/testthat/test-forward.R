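test_that("steady-state signal obeys the spoiled gradient-echo closed form", {
  # full relaxation
  expect_equal(steady_state_signal(1, 100, 90), 1, tolerance = 1e-10)
  # Ernst condition maximises over a flip-angle grid
  T1 <- 1.3; TR <- 0.8
  grid <- seq(1, 179, by = 0.5)
  s <- vapply(grid, function(a) steady_state_signal(T1, TR, a), 0)
  expect_equal(grid[which.max(s)], ernst_angle(T1, TR), tolerance = 0.5)
  # the short-TR protocol flip choices are near the Ernst angle
  expect_equal(ernst_angle(1.25, 0.8), 59.6, tolerance = 0.5)
  # vectorised over a T1 map, air (T1 = 0) fully relaxed
  m <- steady_state_signal(matrix(c(0, 1.2), 1, 2), 0.8, 60)
  expect_equal(m[1, 1], sin(60 * pi / 180))
})

test_that("predicted sensitivity ratio matches hand evaluation of the closed form", {
  expect_equal(predicted_sensitivity_ratio(2.5, 90, 2.5, 90), 1)
  # hand oracle, written out independently of the implementation
  hand <- function(TRa, fa, TRb, fb, T1 = 1.2) {
    S <- function(TR, fdeg) {
      E <- exp(-TR / T1); a <- fdeg * pi / 180
      sin(a) * (1 - E) / (1 - cos(a) * E)
    }
    S(TRb, fb) / S(TRa, fa) * sqrt(TRa / TRb)
  }
  expect_equal(predicted_sensitivity_ratio(2.5, 90, 0.4, 50),
               hand(2.5, 90, 0.4, 50), tolerance = 1e-12)
  expect_equal(predicted_sensitivity_ratio(2.5, 90, 0.8, 60),
               hand(2.5, 90, 0.8, 60), tolerance = 1e-12)
  # the short-TR prediction is ~15% above unity
  expect_equal(predicted_sensitivity_ratio(2.5, 90, 0.4, 50), 1.15,
               tolerance = 0.005)
  expect_error(predicted_sensitivity_ratio(2.5, 90, 0.7, 50),
               "divisible")
})

test_that("ideal single-slice acquisition inverts to the object by Fourier identity", {
  ph <- fx_phantom(1, 32)
  co <- fx_coils(1, 32, 4)
  sp <- protocol_spec(m = 1, n = 1, R_pe = 1, pf = 1, matrix = 32)
  mux <- do.call(simulate_mux_acquisition,
                 c(list(ph, co, sp, noise_sigma = 0, slices = 1,
                        use_steady_state = FALSE), ideal_sim))
  rec <- reconstruct(mux)
  truth <- rss_combine(lapply(co$maps[[1]], function(cm)
    cm * ph$slices[[1]]))
  expect_lt(rel_rmse(rec$slice_images[["1"]], truth), 1e-12)
})

test_that("SIR slots carry their own slices (supports match single-slice oracle)", {
  ph <- fx_phantom(2, 32)
  co <- fx_coils(2, 32, 4)
  sp <- protocol_spec(m = 2, n = 1, R_pe = 1, pf = 1, matrix = 32)
  mux <- do.call(simulate_mux_acquisition,
                 c(list(ph, co, sp, noise_sigma = 0,
                        use_steady_state = FALSE), ideal_sim))
  slots <- demux_sir(mux)
  for (j in 1:2) {
    K <- matrix(0 + 0i, 32, 32)
    K[, mux$acq_ky] <- slots[[j]][[1]]
    img <- ift2c(K)
    o1 <- Mod(co$maps[[j]][[1]] * ph$slices[[j]])
    o2 <- Mod(co$maps[[3 - j]][[1]] * ph$slices[[3 - j]])
    expect_lt(rel_rmse(Mod(img), o1), 1e-10)
    expect_gt(rel_rmse(Mod(img), o2), 1e3 * rel_rmse(Mod(img), o1))
  }
})

test_that("constant off-resonance shifts the image along PE by the analytic amount", {
  N <- 32
  df <- 60
  ph <- make_brain_phantom(1, N, 192, seed = 1)
  img <- matrix(0 + 0i, N, N); img[17, 17] <- 1
  ph$slices[[1]] <- img
  ph$off_resonance[[1]] <- matrix(df, N, N)
  ph$fat_fraction[[1]] <- matrix(0, N, N)
  co <- make_coil_sensitivities(ph, 1, mode = "uniform")
  sp <- protocol_spec(m = 1, n = 1, R_pe = 1, pf = 1, matrix = N,
                      bw_per_pixel = 1302, t_ramp_total = 0)
  mux <- simulate_mux_acquisition(ph, co, sp, use_t2s = FALSE,
                                  use_fat_shift = FALSE,
                                  use_steady_state = FALSE)
  rec <- reconstruct(mux)
  w <- Mod(rec$slice_images[["1"]])^2
  cy <- sum(w * col(w)) / sum(w)
  shift_pred <- df * echo_spacing(sp) * N  # voxels
  expect_equal(abs(cy - 17), shift_pred, tolerance = 0.05)
})

test_that("acquisition energy is conserved and linear in the object", {
  ph <- fx_phantom(2, 32)
  co <- fx_coils(2, 32, 4)
  sp2 <- protocol_spec(m = 2, n = 1, R_pe = 1, pf = 1, matrix = 32)
  sp1 <- protocol_spec(m = 1, n = 1, R_pe = 1, pf = 1, matrix = 32)
  mux <- do.call(simulate_mux_acquisition,
                 c(list(ph, co, sp2, noise_sigma = 0), ideal_sim))
  e_mux <- sum(Mod(mux$data)^2)
  e_single <- sum(vapply(1:2, function(s) {
    mx <- do.call(simulate_mux_acquisition,
                  c(list(ph, co, sp1, noise_sigma = 0, slices = s),
                    ideal_sim))
    sum(Mod(mx$data)^2)
  }, 0))
  expect_rel(e_mux, e_single, 1e-10)

  # linearity: doubling the object doubles the k-space
  ph2 <- ph
  ph2$slices <- lapply(ph$slices, function(s) 2 * s)
  mux2 <- do.call(simulate_mux_acquisition,
                  c(list(ph2, co, sp2, noise_sigma = 0), ideal_sim))
  expect_lt(max(Mod(mux2$data - 2 * mux$data)), 1e-10)
})

test_that("simulation errors and determinism behave as specified", {
  ph <- fx_phantom(2, 32)
  co <- fx_coils(2, 32, 4)
  sp <- protocol_spec(m = 2, n = 2, matrix = 32)
  expect_error(simulate_mux_acquisition(ph, co, sp), "m\\*n")
  sp64 <- protocol_spec(matrix = 64)
  expect_error(simulate_mux_acquisition(ph, co, sp64), "matrix")

  spn <- protocol_spec(m = 1, n = 1, matrix = 32)
  m1 <- simulate_mux_acquisition(ph, co, spn, seed = 9, noise_sigma = 0.1,
                                 slices = 1)
  m2 <- simulate_mux_acquisition(ph, co, spn, seed = 9, noise_sigma = 0.1,
                                 slices = 1)
  expect_identical(m1$data, m2$data)
  m3 <- simulate_mux_acquisition(ph, co, spn, seed = 10, noise_sigma = 0.1,
                                 slices = 1)
  expect_false(identical(m1$data, m3$data))
})

test_that("SIR fat refocusing fraction vanishes once the displaced band leaves the slab", {
  # conventional spin echo refocuses fat fully
  expect_equal(fat_refocused_fraction(1, 3, B0 = 7, Gs_exc = 10), 1)
  fr <- vapply(1:4, function(m)
    fat_refocused_fraction(m, 3, B0 = 7, Gs_exc = 6), 0)
  expect_true(all(diff(fr) <= 0))
  expect_equal(fr[3], 0)
  # simulated spin-echo acquisition: fat ring energy drops to zero
  ph <- fx_phantom(2, 32)
  co <- fx_coils(2, 32, 4)
  fat_energy <- function(m) {
    sp <- protocol_spec(m = m, n = 1, matrix = 32,
                        sequence_type = "spin-echo", B0 = 7, Gs_exc = 2)
    slices <- seq_len(m)
    ph_m <- if (m == 1) fx_phantom(1, 32) else ph
    mux <- simulate_mux_acquisition(ph_m, co, sp, use_offres = FALSE,
                                    use_t2s = FALSE, use_fat_shift = FALSE,
                                    slices = slices)
    rec <- reconstruct(mux)
    img <- rec$slice_images[["1"]]
    sum(img[ph_m$fat_ring[[1]]]^2) / sum(img^2)
  }
  e1 <- fat_energy(1)
  e2 <- fat_energy(2)
  expect_gt(e1, 0.05)       # fat clearly present in conventional SE
  expect_lt(e2, e1 / 2)     # partially suppressed at m = 2
})

test_that("fMRI series generator reproduces its closed-form temporal SNR", {
  ph <- fx_phantom(2, 32)
  sp <- protocol_spec(TR = 2.5, flip = 90, matrix = 32)
  fs <- simulate_fmri_series(ph, sp, 80, thermal_sigma = 4, seed = 3)
  v <- which(as.numeric(fs$mean_image) > 0.5)
  tsnr <- colMeans(fs$series[, v]) / apply(fs$series[, v], 2, sd)
  pred <- as.numeric(fs$mean_image)[v] / 4
  expect_equal(median(tsnr / pred), 1, tolerance = 0.15)

  f2 <- simulate_fmri_series(ph, sp, 80, thermal_sigma = 4, seed = 3)
  expect_identical(fs$series, f2$series)
})

test_that("temporal SNR across protocols tracks the Bloch signal ratio", {
  ph <- fx_phantom(2, 32)
  gm <- which(unlist(lapply(ph$labels, as.integer)) == 1L)
  tsnr_of <- function(TR, flip, nvol) {
    sp <- protocol_spec(TR = TR, flip = flip, matrix = 32)
    fs <- simulate_fmri_series(ph, sp, nvol, thermal_sigma = 4, seed = 5)
    median(colMeans(fs$series[, gm]) / apply(fs$series[, gm], 2, sd))
  }
  r_meas <- tsnr_of(0.4, 50, 300) / tsnr_of(2.5, 90, 300)
  gm_t1 <- 1.3  # phantom gray-matter T1
  r_pred <- steady_state_signal(gm_t1, 0.4, 50) /
    steady_state_signal(gm_t1, 2.5, 90)
  expect_equal(r_meas, r_pred, tolerance = 0.05)
})
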