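test_that("resting-state generator is deterministic with closed-form noise level", {
  truth <- make_rsn_truth(dim3 = c(10, 10, 4), n_networks = 2,
                          duration = 120, amp_pct = 0, confound_pct = 0,
                          thermal_sigma = 8, seed = 2)
  d1 <- generate_rsn_dataset(truth, TR = 1, flip = 90, seed = 5)
  d2 <- generate_rsn_dataset(truth, TR = 1, flip = 90, seed = 5)
  expect_identical(d1$series, d2$series)

  # zero-amplitude truth: pure noise about the mean
  v <- which(as.numeric(d1$mean_image) > 0)
  sds <- apply(d1$series[, v], 2, sd)
  expect_equal(median(sds), 8, tolerance = 0.1)
  mns <- colMeans(d1$series[, v])
  expect_equal(median(mns), as.numeric(d1$mean_image)[v[1]],
               tolerance = 0.05)
  expect_error(generate_rsn_dataset(truth, TR = 200), "TR")
})

test_that("confounds alias to the predicted frequencies", {
  truth <- make_rsn_truth(dim3 = c(8, 8, 2), n_networks = 1,
                          duration = 600, amp_pct = 0, confound_pct = 5,
                          thermal_sigma = 0.01, cardiac_hz = 1,
                          phase_walk_sd = 0, seed = 4)
  peak_freq <- function(TR) {
    ds <- generate_rsn_dataset(truth, TR = TR, flip = 90, seed = 6,
                               slice_offsets = FALSE)
    x <- ds$confound_regressors[, "cardiac"]
    sp <- Mod(fft(x - mean(x)))^2
    n <- length(x)
    f <- (seq_len(n) - 1) / (n * TR)
    half <- seq_len(floor(n / 2) + 1)   # include the Nyquist bin
    f[half][which.max(sp[half])]
  }
  # 1 Hz sampled at TR 2.5 s folds to |1 - round(2.5)/2.5| = 0.2 Hz
  expect_equal(peak_freq(2.5), 0.2, tolerance = 0.02)
  # at TR 0.4 s (Nyquist 1.25 Hz) it appears at its true 1 Hz
  expect_equal(peak_freq(0.4), 1.0, tolerance = 0.02)
})

test_that("preprocessing removes drift and smooths by the stated kernel", {
  dim3 <- c(8, 8, 2)
  V <- prod(dim3)
  nt <- 300; TR <- 2
  # constant series: untouched (mean preserved)
  const <- matrix(5, nt, V); attr(const, "dim3") <- dim3
  out <- preprocess_series(const, TR, fwhm_mm = 5, voxel_mm = 3)
  expect_equal(out[, 1], rep(5, nt), tolerance = 1e-10)

  # a 600 s period drift is attenuated > 90%
  tt <- (seq_len(nt) - 1) * TR
  drift <- sin(2 * pi * tt / 600)
  ser <- matrix(drift, nt, V); attr(ser, "dim3") <- dim3
  hp <- preprocess_series(ser, TR, fwhm_mm = NULL)
  expect_lt(sd(hp[, 1]) / sd(drift), 0.1)
  # a 20 s period signal passes
  fast <- sin(2 * pi * tt / 20)
  ser2 <- matrix(fast, nt, V); attr(ser2, "dim3") <- dim3
  hp2 <- preprocess_series(ser2, TR, fwhm_mm = NULL)
  expect_gt(sd(hp2[, 1]) / sd(fast), 0.9)
  expect_error(preprocess_series(ser[1:50, ], TR), "shorter")

  # delta image smoothed to a Gaussian of the stated width
  dim3b <- c(21, 21, 1)
  delta <- matrix(0, 2, prod(dim3b))
  delta[, (11 - 1) * 21 + 11] <- 1
  attr(delta, "dim3") <- dim3b
  sm <- preprocess_series(delta, TR = 1, highpass_s = NULL,
                          fwhm_mm = 5, voxel_mm = 3)
  img <- matrix(sm[1, ], 21, 21)
  sd_vox <- 5 / 2.355 / 3
  prof <- img[, 11] / max(img)
  pred <- exp(-((1:21) - 11)^2 / (2 * sd_vox^2))
  expect_equal(prof, pred, tolerance = 0.02)
})

test_that("group-PCA concatenation yields scaled stacked eigenmaps", {
  set.seed(8)
  mk <- function(nt) matrix(rnorm(nt * 50), nt, 50)
  ds <- list(mk(40), 3 * mk(40), 0.2 * mk(40))
  gp <- concat_group_pca(ds, n_components = 20)
  expect_equal(nrow(gp$maps), 60)
  expect_equal(ncol(gp$maps), 50)
  # blocks scaled to a common overall variance
  expect_equal(gp$block_variance / gp$block_variance[1], rep(1, 3),
               tolerance = 1e-9)

  # full-rank reduction is lossless: data rows lie in the map row space
  X <- mk(20)
  gp1 <- concat_group_pca(list(X), n_components = 20)
  Xc <- sweep(X, 2, colMeans(X))
  proj <- Xc %*% MASS::ginv(gp1$maps) %*% gp1$maps
  expect_lt(max(abs(proj - Xc)), 1e-8)
  expect_error(concat_group_pca(list(X), n_components = 21),
               "exceeds")
})

test_that("dual regression recovers an exactly representable dataset", {
  set.seed(9)
  V <- 200; K <- 3; nt <- 60
  maps <- matrix(rnorm(K * V), K, V)
  tcs <- scale(matrix(rnorm(nt * K), nt, K))
  ser <- tcs %*% maps
  dr <- dual_regression(ser, maps, demean = FALSE)
  expect_equal(abs(diag(cor(dr$timecourses, tcs))), rep(1, K),
               tolerance = 1e-8)
  expect_lt(max(abs(dr$pe %*% t(dr$pe) / V -
                      maps %*% t(maps) / V)), 0.15)
  # PE at the strongest voxel reproduces the map value (unit-variance tc)
  expect_equal(as.numeric(dr$pe), as.numeric(maps), tolerance = 1e-6)

  # collinear maps are rejected with a condition diagnostic
  bad <- rbind(maps, maps[1, ])
  expect_error(dual_regression(ser, bad), "collinear")
})

test_that("single regression equals multiple regression only for orthogonal designs", {
  set.seed(10)
  nt <- 80; V <- 120
  X <- qr.Q(qr(matrix(rnorm(nt * 3), nt, 3)))  # orthogonal columns
  B <- matrix(rnorm(3 * V), 3, V)
  Y <- X %*% B
  multi <- muxepi:::temporal_regression(Y, X)
  sing <- single_regression(Y, X, demean = FALSE)
  expect_equal(sing$pe, multi$pe, tolerance = 1e-8)

  # correlated regressors: single regression maps leak between networks
  t1 <- scale(rnorm(nt))
  t2 <- scale(0.8 * t1 + 0.6 * rnorm(nt))
  maps <- rbind(c(rep(1, 60), rep(0, 60)), c(rep(0, 60), rep(1, 60)))
  Y2 <- cbind(t1, t2) %*% maps
  m2 <- muxepi:::temporal_regression(Y2, cbind(t1, t2))
  s2 <- single_regression(Y2, cbind(t1, t2), demean = FALSE)
  leak_multi <- mean(abs(m2$pe[1, 61:120]))
  leak_single <- mean(abs(s2$pe[1, 61:120]))
  expect_gt(leak_single, leak_multi + 0.1)

  expect_error(single_regression(Y2, cbind(t1, 0 * t2)), "degenerate")
})

test_that("network maps are recovered from data at the study's CNR", {
  truth <- make_rsn_truth(dim3 = c(16, 16, 8), n_networks = 5,
                          duration = 600, seed = 3)
  ds <- generate_rsn_dataset(truth, TR = 2.5, flip = 90, seed = 11)
  ser <- preprocess_series(ds$series, TR = 2.5)
  V <- prod(truth$dim3)
  maps <- t(vapply(truth$spatial_maps, as.numeric, numeric(V)))
  dr <- dual_regression(ser, maps)
  spat <- vapply(1:5, function(k)
    cor(dr$z[k, ], as.numeric(truth$spatial_maps[[k]])), 0)
  expect_true(all(spat > 0.9))
})

test_that("stage-2 amplitude estimates are unbiased over repeated realisations", {
  truth <- make_rsn_truth(dim3 = c(12, 12, 4), n_networks = 2,
                          duration = 300, amp_pct = 1, confound_pct = 0,
                          thermal_sigma = 10, seed = 6)
  V <- prod(truth$dim3)
  maps <- t(vapply(truth$spatial_maps, as.numeric, numeric(V)))
  peak <- apply(maps, 1, which.max)
  mean_flat <- NULL
  ratios <- vapply(1:50, function(sd) {
    ds <- generate_rsn_dataset(truth, TR = 1.5, flip = 75, seed = 100 + sd)
    # regress the true (sampled, unit-variance) timecourses
    X <- scale(ds$network_tcs)
    fit <- muxepi:::temporal_regression(
      sweep(ds$series, 2, colMeans(ds$series)), X)
    mean_flat <<- as.numeric(ds$mean_image)
    mean(vapply(1:2, function(k)
      100 * fit$pe[k, peak[k]] / mean_flat[peak[k]], 0))
  }, 0)
  expect_equal(mean(ratios), truth$amp_pct, tolerance = 0.05)
})
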