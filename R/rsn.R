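# Resting-state fMRI sensitivity pipeline on synthetic 4D data:
# ground-truth generator (networks + physiological confounds + thermal
# noise), preprocessing (highpass, smoothing), group-PCA concatenation,
# dual and single regression, and the Bloch-equation sensitivity
# predictor.  The mixture-model z calibration lives in ggm.R.

#' Construct resting-state ground truth
#'
#' Defines the synthetic study conditions: `n_networks` spatial networks
#' (Gaussian blobs, peak fractional BOLD amplitude `amp_pct` percent of
#' the mean signal) with smooth unit-variance timecourses band-limited
#' below ~0.1 Hz, plus cardiac (~1 Hz) and respiratory (~0.3 Hz)
#' confound processes with their own spatial weight maps.  Confounds are
#' narrowband oscillators with a Brownian phase walk (beat-to-beat
#' variability), so their autocorrelation decays over a few seconds --
#' the property that makes their sampling rate matter.  All series are
#' generated on a fine 20 Hz grid and later sampled at each protocol's
#' TR (aliasing arises naturally).
#'
#' @param dim3 integer grid dimensions `c(nx, ny, nz)`.
#' @param n_networks number of networks.
#' @param duration run duration (s).
#' @param amp_pct peak network amplitude, % of mean signal.
#' @param confound_pct peak confound amplitude, % of mean signal.
#' @param thermal_sigma thermal noise sd in raw signal units.
#' @param cardiac_hz,resp_hz confound centre frequencies (Hz).
#' @param phase_walk_sd sd of the per-second Brownian phase increment
#'   (rad/sqrt(s)) of the confound oscillators.
#' @param seed RNG seed.
#' @return object of class `rsn_truth`.
#' @export
make_rsn_truth <- function(dim3 = c(16, 16, 8), n_networks = 5,
                           duration = 600, amp_pct = 1,
                           confound_pct = 1, thermal_sigma = 20,
                           cardiac_hz = 1.0, resp_hz = 0.3,
                           phase_walk_sd = 1.0, seed = 1) {
  set.seed(as.integer(seed))
  dt <- 0.05
  nt_fine <- round(duration / dt)
  tfine <- (seq_len(nt_fine) - 1) * dt

  nx <- dim3[1]; ny <- dim3[2]; nz <- dim3[3]
  # ellipsoidal brain mask
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  G <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  r2 <- ((G$x - cx) / (0.45 * nx))^2 + ((G$y - cy) / (0.45 * ny))^2 +
    ((G$z - cz) / (0.48 * nz))^2
  mask <- array(r2 <= 1, dim3)

  blob <- function(centre, sd_vox) {
    d2 <- ((G$x - centre[1])^2 + (G$y - centre[2])^2 +
             (G$z - centre[3])^2) / (2 * sd_vox^2)
    array(exp(-d2), dim3)
  }
  # network centres spread inside the mask
  maps <- vector("list", n_networks)
  for (k in seq_len(n_networks)) {
    repeat {
      ctr <- c(stats::runif(1, 0.25 * nx, 0.75 * nx),
               stats::runif(1, 0.25 * ny, 0.75 * ny),
               stats::runif(1, 0.25 * nz, 0.75 * nz))
      if (mask[round(ctr[1]), round(ctr[2]), round(ctr[3])]) break
    }
    m <- blob(ctr, 0.15 * max(nx, ny))
    m[!mask] <- 0
    maps[[k]] <- amp_pct * m / max(m)
  }

  # smooth unit-variance network timecourses: low-pass filtered noise
  lp_tc <- function(cut_hz) {
    x <- stats::rnorm(nt_fine)
    X <- stats::fft(x)
    f <- c(seq(0, floor(nt_fine / 2)),
           seq(-ceiling(nt_fine / 2) + 1, -1)) / (nt_fine * dt)
    X[abs(f) > cut_hz] <- 0
    y <- Re(stats::fft(X, inverse = TRUE)) / nt_fine
    as.numeric(scale(y))
  }
  tcs <- vapply(seq_len(n_networks), function(k) lp_tc(0.1),
                numeric(nt_fine))

  osc <- function(f0) {
    dphi <- stats::rnorm(nt_fine, sd = phase_walk_sd * sqrt(dt))
    phi <- 2 * pi * f0 * tfine + cumsum(dphi) +
      2 * pi * stats::runif(1)
    as.numeric(scale(sin(phi)))
  }
  cardiac <- osc(cardiac_hz)
  resp <- osc(resp_hz)
  # cardiac weighting strongest near the centre (vessel-like), resp
  # global over the brain
  cmap <- blob(c(cx, cy, cz), 0.12 * max(nx, ny)); cmap[!mask] <- 0
  cmap <- confound_pct * cmap / max(cmap)
  rmap <- array(0, dim3); rmap[mask] <- confound_pct

  out <- list(dim3 = dim3, mask = mask, n_networks = n_networks,
              spatial_maps = maps, timecourses = tcs,
              confounds = list(cardiac = cardiac, resp = resp),
              confound_maps = list(cardiac = cmap, resp = rmap),
              confound_hz = c(cardiac = cardiac_hz, resp = resp_hz),
              thermal_sigma = thermal_sigma, duration = duration,
              dt = dt, t_fine = tfine, amp_pct = amp_pct,
              confound_pct = confound_pct, seed = as.integer(seed))
  class(out) <- "rsn_truth"
  out
}

#' @export
print.rsn_truth <- function(x, ...) {
  cat(sprintf(
    "RSN ground truth: %dx%dx%d grid, %d networks, %g s at %g%% amplitude\n",
    x$dim3[1], x$dim3[2], x$dim3[3], x$n_networks, x$duration, x$amp_pct))
  invisible(x)
}

#' Generate a synthetic resting-state 4D dataset
#'
#' Samples the [make_rsn_truth()] processes at one protocol's TR:
#' `series = M * (1 + sum_k map_k tc_k/100 + confounds/100) + noise`,
#' where the mean level `M` carries the steady-state Bloch amplitude for
#' (TR, flip, T1) so image SNR tracks the per-volume signal, and the
#' thermal noise sd is constant per sample regardless of TR.  Each slice
#' is acquired at a different time within the TR, so confound terms in
#' the data are sampled at slice-shifted times while the returned
#' confound regressors are sampled at the volume reference time -- at
#' long TR the slice spread decorrelates the fast confounds from any
#' single regressor.
#'
#' @param truth an `rsn_truth`.
#' @param TR repetition time (s).
#' @param flip flip angle (degrees).
#' @param T1 assumed tissue T1 (s).
#' @param mean_level fully relaxed mean signal (a.u.).
#' @param seed RNG seed (noise only).
#' @param slice_offsets apply within-TR slice acquisition time offsets
#'   to the confound terms.
#' @return list: `series` (`nx*ny*nz x n_vols` matrix with a `dim3`
#'   attribute), `mean_image`, `confound_regressors`
#'   (`n_vols x 2`), `network_tcs` (sampled truth timecourses), `TR`,
#'   `n_vols`, `truth`.
#' @export
generate_rsn_dataset <- function(truth, TR, flip = 90, T1 = 1.2,
                                 mean_level = 1000, seed = 1,
                                 slice_offsets = TRUE) {
  stopifnot(inherits(truth, "rsn_truth"))
  if (TR <= 0 || TR > truth$duration)
    stop("invalid TR for the given duration")
  n_vols <- floor(truth$duration / TR + 1e-9)
  if (n_vols < 3) stop("duration/TR yields too few volumes")
  dim3 <- truth$dim3
  nz <- dim3[3]
  V <- prod(dim3)
  set.seed(as.integer(seed))

  t_vol <- (seq_len(n_vols) - 1) * TR
  fine_at <- function(tt) {
    i <- pmin(pmax(round(tt / truth$dt) + 1, 1), length(truth$t_fine))
    i
  }
  S <- steady_state_signal(T1, TR, flip)
  M <- mean_level * S
  mean_img <- array(0, dim3); mean_img[truth$mask] <- M

  tc_net <- vapply(seq_len(truth$n_networks), function(k)
    truth$timecourses[fine_at(t_vol), k], numeric(n_vols))
  conf_ref <- cbind(cardiac = truth$confounds$cardiac[fine_at(t_vol)],
                    resp = truth$confounds$resp[fine_at(t_vol)])

  series <- base::matrix(0, V, n_vols)
  net_flat <- vapply(truth$spatial_maps, as.numeric, numeric(V))
  mean_flat <- as.numeric(mean_img)
  bold <- net_flat %*% t(tc_net) / 100           # V x n_vols fractional
  series <- series + mean_flat * (1 + bold)
  cmaps <- vapply(truth$confound_maps, as.numeric, numeric(V))
  zidx <- rep(seq_len(nz), each = dim3[1] * dim3[2])
  for (z in seq_len(nz)) {
    off <- if (slice_offsets) TR * (z - 1) / nz else 0
    conf_z <- cbind(truth$confounds$cardiac[fine_at(t_vol + off)],
                    truth$confounds$resp[fine_at(t_vol + off)])
    vsel <- which(zidx == z)
    series[vsel, ] <- series[vsel, ] +
      (mean_flat[vsel] * cmaps[vsel, , drop = FALSE] / 100) %*% t(conf_z)
  }
  series <- series + base::matrix(stats::rnorm(V * n_vols,
                                               sd = truth$thermal_sigma),
                                  V, n_vols)
  series <- t(series)                             # n_vols x V
  attr(series, "dim3") <- dim3
  list(series = series, mean_image = mean_img,
       confound_regressors = conf_ref, network_tcs = tc_net,
       TR = TR, n_vols = n_vols, flip = flip, T1 = T1,
       bloch_signal = S, truth = truth)
}

#' Preprocess a resting-state series
#'
#' Removes temporal drift with a discrete-cosine highpass of full width
#' `highpass_s` seconds (components slower than `1/highpass_s` Hz are
#' projected out; the temporal mean is preserved) and applies per-volume
#' Gaussian spatial smoothing of `fwhm_mm` full width at half maximum.
#' @param series `n_vols x V` matrix with a `dim3` attribute (as
#'   produced by [generate_rsn_dataset()]).
#' @param TR repetition time (s).
#' @param highpass_s highpass full width (s); `NULL` disables.
#' @param fwhm_mm smoothing kernel FWHM (mm); `NULL` disables.
#' @param voxel_mm voxel size (mm).
#' @return filtered series, same shape and attributes.
#' @export
preprocess_series <- function(series, TR, highpass_s = 200, fwhm_mm = 5,
                              voxel_mm = 3) {
  nt <- nrow(series)
  if (!is.null(highpass_s)) {
    if (nt * TR <= highpass_s)
      stop("series shorter than the highpass width")
    K <- floor(2 * nt * TR / highpass_s)
    if (K >= 1) {
      tt <- seq_len(nt) - 0.5
      B <- vapply(seq_len(K), function(k)
        cos(pi * k * tt / nt), numeric(nt))
      B <- qr.Q(qr(B))
      series <- series - B %*% (t(B) %*% series)
    }
  }
  if (!is.null(fwhm_mm) && fwhm_mm > 0) {
    dim3 <- attr(series, "dim3")
    if (is.null(dim3)) stop("series lacks a dim3 attribute")
    sd_vox <- fwhm_mm / 2.355 / voxel_mm
    sm <- lapply(dim3, function(L) gauss_smooth_matrix(L, sd_vox))
    V <- prod(dim3)
    for (v in seq_len(nt)) {
      vol <- array(series[v, ], dim3)
      vol <- smooth3d_apply(vol, sm)
      series[v, ] <- as.numeric(vol)
    }
  }
  series
}

# Row-normalised 1D Gaussian smoothing matrix (edge-renormalised so
# constants are preserved).
gauss_smooth_matrix <- function(L, sd_vox) {
  if (sd_vox <= 0) return(diag(L))
  idx <- seq_len(L)
  S <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sd_vox^2)))
  S[abs(outer(idx, idx, "-")) > ceiling(3 * sd_vox)] <- 0
  S / rowSums(S)
}

smooth3d_apply <- function(vol, sm) {
  d <- dim(vol)
  # x
  vol <- array(sm[[1]] %*% base::matrix(vol, d[1], d[2] * d[3]), d)
  # y
  vol <- aperm(array(sm[[2]] %*% base::matrix(aperm(vol, c(2, 1, 3)),
                                              d[2], d[1] * d[3]),
                     c(d[2], d[1], d[3])), c(2, 1, 3))
  # z
  vol <- aperm(array(sm[[3]] %*% base::matrix(aperm(vol, c(3, 1, 2)),
                                              d[3], d[1] * d[2]),
                     c(d[3], d[1], d[2])), c(2, 3, 1))
  vol
}

#' Group-PCA concatenation of multiple datasets
#'
#' Reduces each dataset to its top `n_components` principal components,
#' scales every dataset's component block to the same overall variance,
#' and temporally concatenates the spatial eigenmaps: `n_datasets *
#' n_components` rows of spatial maps holding the strongest signals of
#' all datasets (the input usually handed to a group ICA).
#' @param datasets list of `n_vols x V` matrices (equal V).
#' @param n_components components kept per dataset; must not exceed any
#'   dataset's timepoint count.
#' @return list: `maps` (`n_datasets*n_components x V`),
#'   `timecourses` (per dataset, `n_vols x n_components`),
#'   `block_variance` (after scaling; equal by construction),
#'   `n_components`.
#' @export
concat_group_pca <- function(datasets, n_components = 200) {
  if (!length(datasets)) stop("need at least one dataset")
  V <- ncol(datasets[[1]])
  blocks <- list(); tcs <- list(); bvar <- numeric(length(datasets))
  for (i in seq_along(datasets)) {
    X <- datasets[[i]]
    if (ncol(X) != V) stop("datasets must share the voxel grid")
    if (n_components > nrow(X))
      stop("n_components exceeds the timepoint count of dataset ", i)
    X <- sweep(X, 2, colMeans(X))
    sv <- svd(X, nu = n_components, nv = n_components)
    d <- sv$d[seq_len(n_components)]
    maps_i <- d * t(sv$v)                     # K x V spatial eigenmaps
    tcs[[i]] <- sv$u
    blocks[[i]] <- maps_i
    bvar[i] <- sum(d^2)
  }
  target <- bvar[1]
  for (i in seq_along(blocks)) {
    sc <- sqrt(target / bvar[i])
    blocks[[i]] <- blocks[[i]] * sc
    bvar[i] <- bvar[i] * sc^2
  }
  list(maps = do.call(rbind, blocks), timecourses = tcs,
       block_variance = bvar, n_components = n_components)
}

#' Dual regression of group maps into a dataset
#'
#' Stage 1: each volume is spatially regressed on the group maps
#' (multiple regression), giving one timecourse per map; these are
#' normalised to unit variance so stage-2 coefficients carry amplitude
#' information.  Stage 2: every voxel's timeseries is regressed on the
#' normalised timecourses, giving parameter-estimate (amplitude) maps,
#' residual standard deviations and ordinary-least-squares z-statistic
#' maps.
#' @param series `n_vols x V` matrix.
#' @param group_maps `K x V` matrix of spatial maps, linearly
#'   independent over the grid.
#' @param demean remove each voxel's temporal mean first (default TRUE).
#' @return list: `timecourses` (`n_vols x K`, unit variance), `pe`
#'   (`K x V`), `z` (`K x V`), `resid_sd` (length V), `dof`.
#' @export
dual_regression <- function(series, group_maps, demean = TRUE) {
  K <- nrow(group_maps)
  if (ncol(series) != ncol(group_maps))
    stop("series and maps differ in voxel count")
  M <- group_maps
  G <- M %*% t(M)
  if (rcond(G) < 1e-10)
    stop("group maps are collinear (condition number ",
         format(1 / rcond(G), digits = 3), ")")
  Y <- series
  if (demean) Y <- sweep(Y, 2, colMeans(Y))
  tc <- Y %*% t(M) %*% solve(G)                 # n_vols x K
  sdv <- apply(tc, 2, stats::sd)
  if (any(sdv == 0)) stop("degenerate (constant) stage-1 timecourse")
  tc <- sweep(tc, 2, sdv, "/")
  fit <- temporal_regression(Y, tc)
  c(list(timecourses = tc), fit)
}

# Multiple temporal regression of every voxel on design X (n_vols x K).
temporal_regression <- function(Y, X) {
  nt <- nrow(Y); K <- ncol(X)
  XtX <- crossprod(X)
  XtXinv <- solve(XtX)
  B <- XtXinv %*% crossprod(X, Y)               # K x V
  resid <- Y - X %*% B
  dof <- nt - K
  s2 <- colSums(resid^2) / dof
  se <- sqrt(outer(diag(XtXinv), s2))
  Z <- B / se
  list(pe = B, z = Z, resid_sd = sqrt(s2), dof = dof)
}

#' Single (one-at-a-time) regression
#'
#' Regresses each timecourse into the data independently -- close to a
#' seed-based correlation analysis.  Identical to the multiple
#' regression when the regressors are orthogonal; for correlated
#' networks the maps overlap instead of separating.
#' @param series `n_vols x V` matrix.
#' @param timecourses `n_vols x K` matrix (e.g. stage-1 output).
#' @param demean remove voxel means first.
#' @return list of per-regressor results: `pe`, `z` (`K x V`),
#'   `resid_sd` (`K x V`), `dof`.
#' @export
single_regression <- function(series, timecourses, demean = TRUE) {
  X <- as.matrix(timecourses)
  if (any(apply(X, 2, stats::sd) == 0))
    stop("degenerate (constant) regressor")
  Y <- series
  if (demean) Y <- sweep(Y, 2, colMeans(Y))
  K <- ncol(X)
  nt <- nrow(Y)
  pe <- z <- base::matrix(0, K, ncol(Y))
  rsd <- base::matrix(0, K, ncol(Y))
  for (k in seq_len(K)) {
    fit <- temporal_regression(Y, X[, k, drop = FALSE])
    pe[k, ] <- fit$pe
    z[k, ] <- fit$z
    rsd[k, ] <- fit$resid_sd
  }
  list(pe = pe, z = z, resid_sd = rsd, dof = nt - 1)
}

#' Predicted fMRI sensitivity ratio of two protocols
#'
#' Bloch-equation prediction for the raw peak z-statistic of a
#' fixed-duration run: the steady-state signal ratio of the two
#' protocols times the square root of the timepoint-count ratio,
#' `[S(T1, TR_b, flip_b) / S(T1, TR_a, flip_a)] * sqrt(TR_a / TR_b)`.
#' The per-volume signal loss at short TR is balanced by the larger
#' number of samples.
#' @param TR_a,flip_a reference (long-TR) protocol.
#' @param TR_b,flip_b comparison (short-TR) protocol.
#' @param T1 gray-matter T1 (s); default 1.2.
#' @param duration run duration (s); both protocols must tile it into
#'   whole volumes (within one volume).
#' @return predicted sensitivity ratio (b relative to a).
#' @examples
#' predicted_sensitivity_ratio(2.5, 90, 0.4, 50)   # ~1.15
#' @export
predicted_sensitivity_ratio <- function(TR_a, flip_a, TR_b, flip_b,
                                        T1 = 1.2, duration = 600) {
  if (any(c(TR_a, TR_b, T1, duration) <= 0))
    stop("all arguments must be positive")
  for (TR in c(TR_a, TR_b)) {
    n <- duration / TR
    if (abs(n - round(n)) > 1e-6)
      stop("duration is not divisible into whole volumes at TR = ", TR)
  }
  Sa <- steady_state_signal(T1, TR_a, flip_a)
  Sb <- steady_state_signal(T1, TR_b, flip_b)
  (Sb / Sa) * sqrt(TR_a / TR_b)
}
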