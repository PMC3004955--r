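# Reconstruction: SIR de-interleaving, GRAPPA-type multiband slice
# separation (7x7 k-space projection operator), in-plane GRAPPA
# unaliasing, partial-Fourier completion, centred 2D FT and
# root-sum-of-squares coil combination.

#' De-interleave the SIR sub-readouts
#'
#' Each readout period of a SIR acquisition holds `m` temporally
#' sequential sub-readouts.  This splits every echo into its `m` slots
#' (undoing the even-echo time reversal first), the exact inverse of the
#' interleaving -- bit-exact, noise included.
#' @param mux a `mux_kspace` from [simulate_mux_acquisition()].
#' @return list of length `m`; element `j` is a list over coils of
#'   compact k-space matrices `[kx = N, ky = acquired lines]` for SIR
#'   slot `j`.
#' @export
demux_sir <- function(mux) {
  stopifnot(inherits(mux, "mux_kspace"))
  lay <- mux$sir_layout
  m <- lay$m; N <- lay$nx
  d <- dim(mux$data)
  if (d[3] != m * N)
    stop("sample count per echo does not match the SIR layout")
  nc <- d[1]; ne <- d[2]
  data <- mux$data
  if (isTRUE(lay$polarity_flip)) {
    flip_idx <- which(seq_len(ne) %% 2 == 0)
    data[, flip_idx, ] <- data[, flip_idx, rev(seq_len(m * N)),
                               drop = FALSE]
  }
  lapply(seq_len(m), function(j) {
    cols <- (j - 1) * N + seq_len(N)
    lapply(seq_len(nc), function(cc) {
      # -> [kx, ky] compact matrix
      t(data[cc, , cols, drop = TRUE][seq_len(ne), , drop = FALSE])
    })
  })
}

# Inverse of demux_sir (used by the round-trip property tests): rebuilds
# the interleaved [coil, echo, m*N] array from per-slot coil matrices.
interleave_sir <- function(slots, polarity_flip = TRUE) {
  m <- length(slots)
  nc <- length(slots[[1]])
  N <- nrow(slots[[1]][[1]])
  ne <- ncol(slots[[1]][[1]])
  data <- array(0 + 0i, c(nc, ne, m * N))
  for (j in seq_len(m)) for (cc in seq_len(nc))
    data[cc, , (j - 1) * N + seq_len(N)] <- t(slots[[j]][[cc]])
  if (polarity_flip) {
    flip_idx <- which(seq_len(ne) %% 2 == 0)
    data[, flip_idx, ] <- data[, flip_idx, rev(seq_len(m * N)),
                               drop = FALSE]
  }
  data
}

# Multi-coil sliding-window patch matrix.  mats: list over coils of
# [nx, ny] matrices; returns the patch matrix over the positions grid,
# columns ordered (coil, dy, dx).  pad = "none" restricts to interior
# positions (calibration); "wrap" covers every position with periodic
# boundaries (k-space of a discrete object is periodic, so the coil
# modulation acts as a circular convolution); "zero" zero-pads.
im2col_multi <- function(mats, ksz = 7, pad = c("none", "wrap", "zero")) {
  pad <- match.arg(pad)
  h <- (ksz - 1) / 2
  nx <- nrow(mats[[1]]); ny <- ncol(mats[[1]])
  if (pad == "wrap") {
    ix <- c(nx - h + seq_len(h), seq_len(nx), seq_len(h))
    iy <- c(ny - h + seq_len(h), seq_len(ny), seq_len(h))
    mats <- lapply(mats, function(M) M[ix, iy, drop = FALSE])
    xs <- h + seq_len(nx); ys <- h + seq_len(ny)
  } else if (pad == "zero") {
    mats <- lapply(mats, function(M) {
      P <- base::matrix(0 + 0i, nx + 2 * h, ny + 2 * h)
      P[h + seq_len(nx), h + seq_len(ny)] <- M
      P
    })
    xs <- h + seq_len(nx); ys <- h + seq_len(ny)
  } else {
    xs <- (h + 1):(nx - h); ys <- (h + 1):(ny - h)
  }
  npos <- length(xs) * length(ys)
  out <- base::matrix(0 + 0i, npos, length(mats) * ksz * ksz)
  col <- 0L
  for (cc in seq_along(mats)) {
    M <- mats[[cc]]
    for (dy in -h:h) for (dx in -h:h) {
      col <- col + 1L
      out[, col] <- as.vector(M[xs + dx, ys + dy, drop = FALSE])
    }
  }
  out
}

# Ridge-regularised least squares with shared design, solved by QR of
# the augmented system [A; sqrt(lambda) I] (avoids squaring the
# condition number through the normal equations); lambda is relative to
# the mean squared column norm.
ridge_solve <- function(A, B, reg) {
  p <- ncol(A)
  lambda <- reg * sum(Mod(A)^2) / p
  Aaug <- rbind(A, diag(sqrt(lambda) + 0i, p))
  Baug <- rbind(B, base::matrix(0 + 0i, p, ncol(B)))
  qr.coef(qr(Aaug), Baug)
}

#' Calibrate the multiband slice-separation kernel
#'
#' Fits, for each target slice and coil, a complex weight block over a
#' `kernel_size x kernel_size` k-space neighbourhood spanning all coils,
#' mapping sliding patches of the SUM of the single-band calibration
#' k-spaces to the corresponding single-slice, single-coil centre point
#' (a GRAPPA-type projection operator).  Many overlapping regions drawn
#' from the summed data give an overdetermined least-squares system,
#' stabilised by relative Tikhonov regularisation.
#'
#' @param singleband_kspaces named list: one element per slice (any ky
#'   grid, the same for all slices), each a list over coils of
#'   `[kx, ky]` complex matrices.  Pass data on the same ky sampling
#'   grid as the composite the kernel will be applied to.
#' @param kernel_size odd kernel side length (default 7).
#' @param reg relative Tikhonov regularisation.
#' @return object of class `mb_kernel`: `weights` matrix
#'   `[kernel_size^2 * n_coils, n_slices * n_coils]`, slice names,
#'   fit residual (relative), geometry metadata.
#' @export
calibrate_mb_kernel <- function(singleband_kspaces, kernel_size = 7,
                                reg = 1e-10) {
  ns <- length(singleband_kspaces)
  if (ns < 1) stop("no calibration slices given")
  nc <- length(singleband_kspaces[[1]])
  nx <- nrow(singleband_kspaces[[1]][[1]])
  ny <- ncol(singleband_kspaces[[1]][[1]])
  h <- (kernel_size - 1) / 2
  if (nx < kernel_size + 2 || ny < kernel_size + 2)
    stop("calibration region too small for the kernel (under-determined)")
  composite <- lapply(seq_len(nc), function(cc) {
    acc <- 0
    for (s in seq_len(ns)) acc <- acc + singleband_kspaces[[s]][[cc]]
    acc
  })
  # patches at every position, with the same periodic boundary handling
  # used at application time, so the fit covers the whole grid
  A <- im2col_multi(composite, kernel_size, pad = "wrap")
  if (nrow(A) < ncol(A))
    stop("calibration under-determined: ", nrow(A), " patches for ",
         ncol(A), " weights")
  B <- base::matrix(0 + 0i, nrow(A), ns * nc)
  k <- 0L
  for (s in seq_len(ns)) for (cc in seq_len(nc)) {
    k <- k + 1L
    B[, k] <- as.vector(singleband_kspaces[[s]][[cc]])
  }
  W <- ridge_solve(A, B, reg)
  resid <- sqrt(sum(Mod(A %*% W - B)^2) / max(sum(Mod(B)^2),
                                              .Machine$double.eps))
  out <- list(weights = W, kernel_size = kernel_size, reg = reg,
              n_slices = ns, n_coils = nc,
              slice_names = names(singleband_kspaces) %||%
                as.character(seq_len(ns)),
              fit_residual = resid,
              calibration_descriptor = sprintf(
                "%d slices x %d coils, %dx%d grid", ns, nc, nx, ny))
  class(out) <- "mb_kernel"
  out
}

#' @export
print.mb_kernel <- function(x, ...) {
  cat(sprintf(
    "MB separation kernel: %dx%d, %d slices x %d coils, fit resid %.2e\n",
    x$kernel_size, x$kernel_size, x$n_slices, x$n_coils, x$fit_residual))
  invisible(x)
}

#' Apply the multiband separation kernel
#'
#' Sliding-window application of a calibrated [calibrate_mb_kernel()]
#' operator to a composite (slice-summed) multi-coil k-space; boundaries
#' are zero-padded.
#' @param composite_kspace list over coils of `[kx, ky]` matrices on the
#'   same ky grid the kernel was calibrated on.
#' @param kernel an `mb_kernel`.
#' @param boundary `"wrap"` (periodic, matching the discrete-object
#'   k-space) or `"zero"` (zero-padded edges).
#' @return list per slice of lists per coil of separated k-space
#'   matrices.
#' @export
apply_mb_separation <- function(composite_kspace, kernel,
                                boundary = c("wrap", "zero")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(kernel, "mb_kernel"))
  nc <- length(composite_kspace)
  if (nc != kernel$n_coils)
    stop("coil count does not match the kernel")
  nx <- nrow(composite_kspace[[1]]); ny <- ncol(composite_kspace[[1]])
  P <- im2col_multi(composite_kspace, kernel$kernel_size, pad = boundary)
  OUT <- P %*% kernel$weights
  res <- vector("list", kernel$n_slices)
  k <- 0L
  for (s in seq_len(kernel$n_slices)) {
    res[[s]] <- vector("list", nc)
    for (cc in seq_len(nc)) {
      k <- k + 1L
      res[[s]][[cc]] <- base::matrix(OUT[, k], nx, ny)
    }
  }
  names(res) <- kernel$slice_names
  res
}

#' Calibrate an in-plane GRAPPA kernel
#'
#' Standard k-space GRAPPA: for each phase-encode offset `d` in
#' `1..R_pe-1`, fits weights mapping four acquired neighbouring lines
#' (at ky offsets `-R, 0, +R, +2R`) x five kx taps x all coils to the
#' missing point of each target coil, on fully sampled calibration data.
#' @param cal_kspaces list over coils of fully sampled `[N, N]`
#'   calibration k-spaces.
#' @param R_pe in-plane reduction factor.
#' @param reg relative Tikhonov regularisation.
#' @return object of class `inplane_kernel`.
#' @export
calibrate_inplane_kernel <- function(cal_kspaces, R_pe, reg = 1e-10) {
  if (R_pe < 1) stop("R_pe must be >= 1")
  nc <- length(cal_kspaces)
  N <- nrow(cal_kspaces[[1]])
  out <- list(R_pe = as.integer(R_pe), n_coils = nc,
              kx_taps = -2:2, ky_src = c(-1L, 0L, 1L, 2L),
              weights = vector("list", max(R_pe - 1, 0)))
  class(out) <- "inplane_kernel"
  if (R_pe == 1) return(out)
  kxs <- out$kx_taps
  ky_src <- out$ky_src * R_pe
  xs <- 3:(N - 2)
  y0s <- (2 * R_pe + 1):(N - 2 * R_pe - (R_pe - 1))
  if (length(y0s) < 8) stop("insufficient calibration lines for R = ", R_pe)
  npos <- length(xs) * length(y0s)
  A <- base::matrix(0 + 0i, npos, nc * length(ky_src) * length(kxs))
  col <- 0L
  for (cc in seq_len(nc)) for (dy in ky_src) for (dx in kxs) {
    col <- col + 1L
    A[, col] <- as.vector(cal_kspaces[[cc]][xs + dx, y0s + dy,
                                            drop = FALSE])
  }
  for (d in seq_len(R_pe - 1)) {
    B <- base::matrix(0 + 0i, npos, nc)
    for (cc in seq_len(nc))
      B[, cc] <- as.vector(cal_kspaces[[cc]][xs, y0s + d, drop = FALSE])
    out$weights[[d]] <- ridge_solve(A, B, reg)
  }
  out
}

#' Fill missing phase-encode lines with an in-plane GRAPPA kernel
#'
#' Synthesises the skipped lines of an `R_pe`-undersampled k-space from
#' the acquired ones using a [calibrate_inplane_kernel()] fit; `R_pe = 1`
#' is the identity.  Lines outside the partial-Fourier window stay zero.
#' @param kspaces list over coils of `[N, N]` k-spaces with only the
#'   acquired lines non-missing.
#' @param acq_ky indices of acquired ky lines.
#' @param kernel an `inplane_kernel`.
#' @return list over coils of filled `[N, N]` k-spaces.
#' @export
inplane_unalias <- function(kspaces, acq_ky, kernel) {
  stopifnot(inherits(kernel, "inplane_kernel"))
  R <- kernel$R_pe
  if (R == 1) return(kspaces)
  nc <- length(kspaces)
  if (nc != kernel$n_coils) stop("coil count does not match the kernel")
  N <- nrow(kspaces[[1]])
  kxs <- kernel$kx_taps
  ky_src <- kernel$ky_src * R
  h <- max(abs(kxs))
  # zero-pad in both directions for boundary handling
  padx <- h; pady <- 2 * R
  padded <- lapply(kspaces, function(K) {
    P <- base::matrix(0 + 0i, N + 2 * padx, N + 2 * pady)
    P[padx + seq_len(N), pady + seq_len(N)] <- K
    P
  })
  lo <- min(acq_ky); hi <- max(acq_ky)
  out <- kspaces
  for (y in seq(lo, hi)) {
    if (y %in% acq_ky) next
    y0 <- max(acq_ky[acq_ky < y])
    d <- y - y0
    if (d >= R) next
    W <- kernel$weights[[d]]
    A <- base::matrix(0 + 0i, N, nrow(W))
    col <- 0L
    for (cc in seq_len(nc)) for (dy in ky_src) for (dx in kxs) {
      col <- col + 1L
      A[, col] <- padded[[cc]][padx + seq_len(N) + dx, pady + y0 + dy]
    }
    fill <- A %*% W
    for (cc in seq_len(nc)) out[[cc]][, y] <- fill[, cc]
  }
  out
}

#' Complete a partial-Fourier k-space
#'
#' The default mode leaves the unsampled early phase-encode lines at
#' zero (zero-filling); `"conjugate"` fills them by Hermitian symmetry
#' `K(-k) = Conj(K(k))`, exact for a real-valued object.  `pf = 1` is
#' the identity.
#' @param kspaces list over coils of `[N, N]` k-spaces.
#' @param pf partial-Fourier fraction in (0.5, 1].
#' @param mode `"zero"` or `"conjugate"`.
#' @return list over coils of completed k-spaces.
#' @export
partial_fourier_fill <- function(kspaces, pf, mode = c("zero", "conjugate")) {
  mode <- match.arg(mode)
  if (pf <= 0.5 || pf > 1) stop("pf must lie in (0.5, 1]")
  if (pf == 1 || mode == "zero") return(kspaces)
  N <- nrow(kspaces[[1]])
  c0 <- floor(N / 2) + 1
  lo <- floor((1 - pf) * N) + 1
  lapply(kspaces, function(K) {
    for (y in seq_len(lo - 1)) {
      ys <- 2 * c0 - y
      if (ys >= 1 && ys <= N) {
        xs <- 2 * c0 - seq_len(N)
        ok <- xs >= 1 & xs <= N
        K[ok, y] <- Conj(K[xs[ok], ys])
      }
    }
    K
  })
}

#' Reconstruct a multiplexed EPI acquisition
#'
#' Full inversion pipeline: SIR de-interleave, per-slot multiband slice
#' separation with a GRAPPA-type kernel calibrated from the supplied
#' single-band data, in-plane GRAPPA unaliasing, partial-Fourier
#' completion, centred 2D inverse FT and root-sum-of-squares coil
#' combination.  Emits `m * n` slice images per shot.
#'
#' @param mux a `mux_kspace`.
#' @param calibration single-band calibration from
#'   [simulate_singleband_calibration()] (fully sampled, per slice per
#'   coil); required when `n > 1` or `R_pe > 1`.
#' @param pf_mode partial-Fourier handling, `"zero"` or `"conjugate"`.
#' @param reg relative regularisation for all kernel fits.
#' @param reference optional list of ground-truth magnitude images (per
#'   shot slice) for RMSE reporting.
#' @return object of class `mux_recon`: `slice_images` (magnitude, named
#'   by phantom slice index), `coil_images` (complex, per slice per
#'   coil), `rmse` (scale-invariant relative RMSE per slice, if
#'   `reference` given), `kernels`, `spec`.
#' @export
reconstruct <- function(mux, calibration = NULL,
                        pf_mode = c("zero", "conjugate"), reg = 1e-10,
                        reference = NULL) {
  pf_mode <- match.arg(pf_mode)
  stopifnot(inherits(mux, "mux_kspace"))
  spec <- mux$spec
  N <- mux$sir_layout$nx
  nc <- dim(mux$data)[1]
  need_cal <- spec$n > 1 || spec$R_pe > 1
  if (need_cal && is.null(calibration))
    stop("[separation] calibration data required for n > 1 or R_pe > 1")

  slots <- demux_sir(mux)
  acq <- mux$acq_ky

  kernels <- list()
  sep <- list()  # per slice: list per coil of compact [N, n_acq]
  for (j in seq_len(spec$m)) {
    group <- mux$mb_groups[[j]]
    if (spec$n == 1) {
      sep[[as.character(group)]] <- slots[[j]]
    } else {
      cal_j <- lapply(as.character(group), function(s) {
        if (is.null(calibration[[s]]))
          stop("[separation] calibration missing for slice ", s)
        lapply(calibration[[s]], function(K) K[, acq, drop = FALSE])
      })
      names(cal_j) <- as.character(group)
      kern <- calibrate_mb_kernel(cal_j, kernel_size = 7, reg = reg)
      kernels[[paste0("mb_slot", j)]] <- kern
      out_j <- apply_mb_separation(slots[[j]], kern)
      for (s in names(out_j)) sep[[s]] <- out_j[[s]]
    }
  }

  slice_names <- as.character(mux$slices)
  coil_images <- list(); slice_images <- list()
  for (s in slice_names) {
    full <- lapply(seq_len(nc), function(cc) {
      K <- base::matrix(0 + 0i, N, N)
      K[, acq] <- sep[[s]][[cc]]
      K
    })
    if (spec$R_pe > 1) {
      kname <- paste0("inplane_", s)
      kern <- calibrate_inplane_kernel(calibration[[s]], spec$R_pe,
                                       reg = reg)
      kernels[[kname]] <- kern
      full <- inplane_unalias(full, acq, kern)
    }
    full <- partial_fourier_fill(full, spec$pf, mode = pf_mode)
    imgs <- lapply(full, ift2c)
    coil_images[[s]] <- imgs
    slice_images[[s]] <- rss_combine(imgs)
  }

  rmse <- NULL
  if (!is.null(reference)) {
    rmse <- vapply(seq_along(slice_names), function(i)
      rel_rmse(slice_images[[slice_names[i]]], reference[[i]]), 0)
    names(rmse) <- slice_names
  }
  out <- list(slice_images = slice_images, coil_images = coil_images,
              rmse = rmse, kernels = kernels, spec = spec,
              slices = mux$slices)
  class(out) <- "mux_recon"
  out
}

#' @export
print.mux_recon <- function(x, ...) {
  cat(sprintf("M-EPI reconstruction: %d slice(s) (m=%d x n=%d, R=%d)\n",
              length(x$slice_images), x$spec$m, x$spec$n, x$spec$R_pe))
  if (!is.null(x$rmse))
    cat("  relative RMSE vs reference: ",
        paste(sprintf("%.3f", x$rmse), collapse = ", "), "\n")
  invisible(x)
}
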