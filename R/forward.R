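# M-EPI acquisition forward model: steady-state signal scaling, per-line
# off-resonance / chemical-shift phase, T2* decay, SIR temporal
# interleaving, multiband slice summation through coil sensitivities,
# in-plane undersampling, partial Fourier and complex receiver noise.

#' Steady-state gradient-echo (spoiled) signal
#'
#' `S = sin(a) (1 - E1) / (1 - cos(a) E1)` with `E1 = exp(-TR/T1)`.
#' Vectorised over `T1` (a map may be passed); nonpositive `T1` yields
#' `E1 = 0` (full relaxation).
#' @param T1 longitudinal relaxation time (s); scalar or array.
#' @param TR repetition time (s).
#' @param flip flip angle (degrees).
#' @return relative signal in `[0, 1]`, same shape as `T1`.
#' @examples
#' steady_state_signal(1.25, 0.8, 60)
#' @export
steady_state_signal <- function(T1, TR, flip) {
  if (TR <= 0) stop("TR must be > 0")
  if (flip <= 0 || flip > 180) stop("flip must lie in (0, 180]")
  a <- flip * pi / 180
  E1 <- ifelse(T1 > 0, exp(-TR / T1), 0)
  sin(a) * (1 - E1) / (1 - cos(a) * E1)
}

#' Ernst angle
#' @inheritParams steady_state_signal
#' @return flip angle (degrees) maximising the steady-state signal.
#' @export
ernst_angle <- function(T1, TR) {
  acos(exp(-TR / T1)) * 180 / pi
}

#' Fraction of fat signal refocused in a SIR spin echo
#'
#' Excitation (gradient `Gs_exc`) selects a fat band displaced by
#' `D = delta * B0 / Gs_exc` from the water slice; the SIR refocusing
#' pulse uses an `m`-times weaker gradient (so one pulse covers the `m`
#' adjacent slices), displacing its fat band by `m * D` and widening it
#' to `m` slice thicknesses.  Only the overlap of the two fat bands is
#' refocused; once `m * D` exceeds the slab the overlap vanishes and fat
#' is inherently suppressed.  Computed for a slice at the slab centre.
#'
#' @param m SIR factor.
#' @param slice_thickness_mm excitation slice thickness (mm).
#' @param delta_ppm chemical shift (ppm).
#' @param B0 field strength (T).
#' @param Gs_exc excitation slice-select gradient (mT/m).
#' @return refocused fat fraction in `[0, 1]`.
#' @export
fat_refocused_fraction <- function(m, slice_thickness_mm = 3,
                                   delta_ppm = FAT_SHIFT_PPM, B0 = 7,
                                   Gs_exc = 20) {
  D <- fat_displacement(delta_ppm, B0, Gs_exc)
  th <- slice_thickness_mm
  lo <- max(D - th / 2, m * D - m * th / 2)
  hi <- min(D + th / 2, m * D + m * th / 2)
  max(0, hi - lo) / th
}

# Acquired phase-encode line indices (1-based, DC at floor(N/2)+1):
# partial Fourier omits the leading (1-pf)*N lines, R_pe keeps every
# R-th of the rest, phased so the DC line is always acquired.
acquired_ky <- function(N, R_pe = 1, pf = 1) {
  c0 <- floor(N / 2) + 1
  lo <- floor((1 - pf) * N) + 1
  ky <- seq(lo, N)
  ky <- ky[(ky - c0) %% R_pe == 0]
  ky
}

# k-space lines of one slice seen by each coil.
# img_eff: complex object already amplitude-scaled; times: per acquired
# line, relative to the k-space centre line; t2s/offres: per-voxel maps.
# Returns array [n_coils, n_lines, N] of kx samples.
slice_klines <- function(img_eff, coil_maps, acq_ky, times,
                         offres = NULL, t2s = NULL, te = 0) {
  N <- nrow(img_eff)
  nc <- length(coil_maps)
  out <- array(0 + 0i, c(nc, length(acq_ky), N))
  coil_imgs <- lapply(coil_maps, function(cm) cm * img_eff)
  for (i in seq_along(acq_ky)) {
    t <- times[i]
    w <- 1
    if (!is.null(offres)) w <- exp(2i * pi * offres * (te + t))
    if (!is.null(t2s)) {
      dec <- ifelse(t2s > 0, exp(-(te + t) / t2s), 0)
      w <- w * dec
    }
    for (cc in seq_len(nc)) {
      K <- ft2c(if (is.matrix(w)) coil_imgs[[cc]] * w else
                  coil_imgs[[cc]] * w)
      out[cc, i, ] <- K[, acq_ky[i]]
    }
  }
  out
}

# Slice indices of each SIR slot: slot j holds slices {j, j+m, ...}
# (SIR slices adjacent in z, multiband partners m slices = FOV/n apart).
mb_slice_groups <- function(m, n, slices) {
  stopifnot(length(slices) == m * n)
  lapply(seq_len(m), function(j) slices[j + m * (seq_len(n) - 1)])
}

#' Simulate one multiplexed EPI shot
#'
#' Produces the acquired object the reconstruction inverts: for each
#' echo (phase-encode line) the readout period holds `m` temporally
#' interleaved sub-readouts; sub-readout (SIR slot) `j` carries the kx
#' line of the composite of the `n` slices excited by the j-th multiband
#' pulse, each seen through every coil, with per-voxel steady-state
#' amplitude, off-resonance phase accrual along the train, T2* decay,
#' fat chemical-shift offset, in-plane undersampling (`R_pe`, partial
#' Fourier) and circular complex Gaussian receiver noise.  Even echoes
#' are time-reversed (EPI readout polarity), which reverses both the kx
#' sample order and the SIR slot order within the readout.
#'
#' @param phantom a [make_brain_phantom()].
#' @param coils a [make_coil_sensitivities()] for the same phantom.
#' @param spec a [protocol_spec()]; `m * n` must not exceed the phantom
#'   slice count.
#' @param seed RNG seed for the noise.
#' @param noise_sigma complex noise standard deviation per coil sample.
#' @param slices slice indices making up the shot (default `1:(m*n)`,
#'   z-ordered).
#' @param use_offres,use_t2s,use_fat_shift,use_steady_state,polarity_flip
#'   stage toggles for the physics terms.
#' @return object of class `mux_kspace` with fields `data` (array
#'   `[coil, echo, m*N]`), `sir_layout`, `mb_groups`, `acq_ky`
#'   (sampling mask), `spec`, `noise_sigma` and timing metadata.
#' @export
simulate_mux_acquisition <- function(phantom, coils, spec, seed = 1,
                                     noise_sigma = 0, slices = NULL,
                                     use_offres = TRUE, use_t2s = TRUE,
                                     use_fat_shift = TRUE,
                                     use_steady_state = TRUE,
                                     polarity_flip = TRUE) {
  stopifnot(inherits(phantom, "mux_phantom"), inherits(coils, "mux_coils"))
  m <- spec$m; n <- spec$n
  N <- phantom$matrix
  if (N != spec$matrix)
    stop("phantom matrix does not match protocol matrix")
  if (coils$matrix != N)
    stop("coil maps do not match the phantom geometry")
  slices <- slices %||% seq_len(m * n)
  if (length(slices) != m * n || max(slices) > length(phantom$slices))
    stop("need exactly m*n valid phantom slices per shot")
  groups <- mb_slice_groups(m, n, slices)
  if (anyDuplicated(unlist(groups)))
    stop("mb_groups must not overlap")

  acq_ky <- acquired_ky(N, spec$R_pe, spec$pf)
  esp <- echo_spacing(spec)
  c0 <- floor(N / 2) + 1
  i_ctr <- which(acq_ky == c0)
  line_times <- (seq_along(acq_ky) - i_ctr) * esp
  te_phase <- if (spec$sequence_type == "gradient-echo") spec$TE else 0

  fat_scale <- if (spec$sequence_type == "spin-echo")
    fat_refocused_fraction(m, phantom$voxel_size_mm,
                           B0 = spec$B0, Gs_exc = spec$Gs_exc) else 1
  df_fat <- fat_offset_hz(B0 = spec$B0)

  data <- array(0 + 0i, c(coils$n_coils, length(acq_ky), m * N))
  for (j in seq_len(m)) {
    slot_times <- line_times + (j - 1) * spec$t_flat
    acc <- array(0 + 0i, c(coils$n_coils, length(acq_ky), N))
    for (s in groups[[j]]) {
      img <- phantom$slices[[s]]
      if (use_steady_state)
        img <- img * steady_state_signal(phantom$T1[[s]], spec$TR,
                                         spec$flip)
      offres <- NULL
      if (use_offres || use_fat_shift) {
        offres <- if (use_offres) phantom$off_resonance[[s]] else
          base::matrix(0, N, N)
        if (use_fat_shift)
          offres <- offres + df_fat * phantom$fat_fraction[[s]]
      }
      if (fat_scale < 1) {
        ff <- phantom$fat_fraction[[s]]
        img <- img * (1 - ff) + img * ff * fat_scale
      }
      t2s <- if (use_t2s) phantom$T2_star[[s]] else NULL
      acc <- acc + slice_klines(img, coils$maps[[s]], acq_ky, slot_times,
                                offres = offres, t2s = t2s, te = te_phase)
    }
    data[, , (j - 1) * N + seq_len(N)] <- acc
  }
  if (polarity_flip) {
    flip_idx <- which(seq_along(acq_ky) %% 2 == 0)
    data[, flip_idx, ] <- data[, flip_idx, rev(seq_len(m * N)),
                               drop = FALSE]
  }
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    data <- data + array(crnorm(length(data), noise_sigma), dim(data))
  }
  out <- list(data = data,
              sir_layout = list(m = m, nx = N, polarity_flip = polarity_flip),
              mb_groups = groups, acq_ky = acq_ky, spec = spec,
              noise_sigma = noise_sigma, line_times = line_times,
              slices = slices)
  class(out) <- "mux_kspace"
  out
}

#' @export
print.mux_kspace <- function(x, ...) {
  cat(sprintf(
    "M-EPI k-space: %d coils, %d echoes x %d samples (m=%d, n=%d, R=%d)\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    x$spec$m, x$spec$n, x$spec$R_pe))
  invisible(x)
}

#' Simulate single-band calibration k-spaces
#'
#' The calibration the multiband separation kernel is trained on: each
#' slice acquired alone (multiband factor 1) with matched SIR timing,
#' fully sampled in phase encode.
#' @inheritParams simulate_mux_acquisition
#' @param slices slice indices to calibrate (default all of the shot,
#'   `1:(m*n)`).
#' @return list `cal[[slice index as character]][[coil]]`: N x N complex
#'   k-space matrices (kx x ky).
#' @export
simulate_singleband_calibration <- function(phantom, coils, spec,
                                            slices = NULL, seed = 1,
                                            noise_sigma = 0,
                                            use_offres = TRUE,
                                            use_t2s = TRUE,
                                            use_fat_shift = TRUE,
                                            use_steady_state = TRUE) {
  stopifnot(inherits(phantom, "mux_phantom"), inherits(coils, "mux_coils"))
  N <- phantom$matrix
  m <- spec$m
  slices <- slices %||% seq_len(m * spec$n)
  acq_ky <- acquired_ky(N, 1, 1)
  esp <- echo_spacing(spec)
  c0 <- floor(N / 2) + 1
  line_times <- (seq_along(acq_ky) - which(acq_ky == c0)) * esp
  te_phase <- if (spec$sequence_type == "gradient-echo") spec$TE else 0
  df_fat <- fat_offset_hz(B0 = spec$B0)
  groups <- mb_slice_groups(m, spec$n, slices)
  if (noise_sigma > 0) set.seed(as.integer(seed))

  out <- list()
  for (j in seq_len(m)) for (s in groups[[j]]) {
    slot_times <- line_times + (j - 1) * spec$t_flat
    img <- phantom$slices[[s]]
    if (use_steady_state)
      img <- img * steady_state_signal(phantom$T1[[s]], spec$TR, spec$flip)
    offres <- NULL
    if (use_offres || use_fat_shift) {
      offres <- if (use_offres) phantom$off_resonance[[s]] else
        base::matrix(0, N, N)
      if (use_fat_shift)
        offres <- offres + df_fat * phantom$fat_fraction[[s]]
    }
    t2s <- if (use_t2s) phantom$T2_star[[s]] else NULL
    kl <- slice_klines(img, coils$maps[[s]], acq_ky, slot_times,
                       offres = offres, t2s = t2s, te = te_phase)
    ks <- lapply(seq_len(coils$n_coils), function(cc) {
      Kf <- base::matrix(0 + 0i, N, N)
      for (i in seq_along(acq_ky)) Kf[, acq_ky[i]] <- kl[cc, i, ]
      if (noise_sigma > 0) Kf <- Kf + base::matrix(crnorm(N * N,
                                                          noise_sigma), N, N)
      Kf
    })
    out[[as.character(s)]] <- ks
  }
  out
}

#' Simulate a magnitude fMRI series from a phantom
#'
#' Per-volume magnitude images scaled by the steady-state signal of
#' (per-voxel T1, TR, flip), with optional BOLD fluctuations applied
#' multiplicatively (percent of the mean) from a resting-state truth
#' object, plus Gaussian thermal noise of constant standard deviation
#' per sample -- so the temporal SNR tracks the Bloch signal level.
#'
#' @param phantom a [make_brain_phantom()].
#' @param spec a [protocol_spec()] supplying TR and flip.
#' @param n_volumes number of volumes.
#' @param rsn_truth optional [make_rsn_truth()] on the grid
#'   `c(matrix, matrix, n_slices)`; `NULL` simulates noise about the
#'   static mean.
#' @param coils optional [make_coil_sensitivities()]; when given, the
#'   mean image is weighted by the root-sum-of-squares sensitivity.
#' @param thermal_sigma noise sd in image units.
#' @param seed RNG seed.
#' @return list: `series` (`n_volumes x V` matrix with `dim3`
#'   attribute), `mean_image` (3D array), `TR`, `bloch_signal` (mean
#'   over tissue of the steady-state scaling).
#' @export
simulate_fmri_series <- function(phantom, spec, n_volumes,
                                 rsn_truth = NULL, coils = NULL,
                                 thermal_sigma = 1, seed = 1) {
  stopifnot(inherits(phantom, "mux_phantom"))
  if (n_volumes < 1) stop("n_volumes must be >= 1")
  N <- phantom$matrix
  nsl <- length(phantom$slices)
  dim3 <- c(N, N, nsl)
  mean_img <- array(0, dim3)
  for (s in seq_len(nsl)) {
    m <- Mod(phantom$slices[[s]]) *
      steady_state_signal(phantom$T1[[s]], spec$TR, spec$flip)
    if (!is.null(coils)) m <- m * coil_rss(coils, s)
    mean_img[, , s] <- m
  }
  if (!is.null(rsn_truth)) {
    stopifnot(inherits(rsn_truth, "rsn_truth"))
    if (!all(rsn_truth$dim3 == dim3))
      stop("rsn_truth grid does not match the phantom geometry")
    if (n_volumes * spec$TR > rsn_truth$duration + 1e-9)
      stop("series duration exceeds the truth duration")
  }
  set.seed(as.integer(seed))
  V <- prod(dim3)
  mean_flat <- as.numeric(mean_img)
  series <- base::matrix(mean_flat, n_volumes, V, byrow = TRUE)
  if (!is.null(rsn_truth)) {
    t_vol <- (seq_len(n_volumes) - 1) * spec$TR
    idx <- pmin(pmax(round(t_vol / rsn_truth$dt) + 1, 1),
                length(rsn_truth$t_fine))
    tc <- vapply(seq_len(rsn_truth$n_networks), function(k)
      rsn_truth$timecourses[idx, k], numeric(n_volumes))
    mp <- vapply(rsn_truth$spatial_maps, as.numeric, numeric(V))
    series <- series * (1 + tc %*% t(mp) / 100)
  }
  series <- series + base::matrix(stats::rnorm(n_volumes * V,
                                               sd = thermal_sigma),
                                  n_volumes, V)
  attr(series, "dim3") <- dim3
  tissue <- mean_img > 0
  list(series = series, mean_image = mean_img, TR = spec$TR,
       bloch_signal = mean(steady_state_signal(
         vapply(seq_len(nsl), function(s)
           mean(phantom$T1[[s]][phantom$labels[[s]] > 0]), 0),
         spec$TR, spec$flip)))
}
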