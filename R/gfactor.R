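# Noise-amplification (g-factor) analysis of coil-encoded unaliasing,
# ROI SNR, the undersampling SNR law, and residual-aliasing metrics.

# Check that fold counts divide the matrix and return fold periods.
fold_periods <- function(N, R_pe, R_ro) {
  if (N %% R_pe != 0 || N %% R_ro != 0)
    stop("matrix size must be divisible by the reduction factors")
  c(px = N / R_ro, py = N / R_pe)
}

#' Analytic SENSE-form g-factor maps
#'
#' For every aliased voxel set (positions folded by `R_pe` along phase
#' encode and `R_ro` along readout, across the simultaneously excited
#' slices of `mb_group`) forms the coil encoding matrix `E` from the
#' sensitivity maps and computes
#' `g = sqrt(diag((E^H E)^-1) * diag(E^H E))` (identity noise
#' covariance).  A rank-deficient set is reported as infinite g.
#'
#' @param coils a [make_coil_sensitivities()].
#' @param mb_group integer vector of slice indices unaliased together.
#' @param R_pe,R_ro in-plane reduction factors along phase encode /
#'   readout.
#' @param mask optional list (per slice of `mb_group`) of logical
#'   matrices restricting the summary statistics.
#' @return object of class `g_factor_map`: per-slice g maps, `method`,
#'   acceleration descriptor, `mean_g`/`max_g` over the mask, and a
#'   `singular` flag.
#' @export
analytic_g_factor <- function(coils, mb_group = 1, R_pe = 1, R_ro = 1,
                              mask = NULL) {
  stopifnot(inherits(coils, "mux_coils"))
  N <- coils$matrix
  p <- fold_periods(N, R_pe, R_ro)
  nsl <- length(mb_group)
  nc <- coils$n_coils
  nset <- nsl * R_pe * R_ro
  maps <- lapply(seq_len(nsl), function(i) base::matrix(NA_real_, N, N))
  singular <- FALSE
  # fold position offsets (0-based)
  offs <- expand.grid(a = seq_len(R_ro) - 1, b = seq_len(R_pe) - 1)
  for (x0 in seq_len(p["px"])) for (y0 in seq_len(p["py"])) {
    xs <- x0 + offs$a * p["px"]
    ys <- y0 + offs$b * p["py"]
    E <- base::matrix(0 + 0i, nc, nset)
    col <- 0L
    pos <- base::matrix(0L, nset, 3)  # slice-idx, x, y
    for (si in seq_len(nsl)) for (k in seq_len(nrow(offs))) {
      col <- col + 1L
      E[, col] <- vapply(seq_len(nc), function(cc)
        coils$maps[[mb_group[si]]][[cc]][xs[k], ys[k]], 0 + 0i)
      pos[col, ] <- c(si, xs[k], ys[k])
    }
    G <- Conj(t(E)) %*% E
    dG <- Re(diag(G))
    Ginv <- tryCatch(solve(G), error = function(e) NULL)
    if (is.null(Ginv) || max(abs(Ginv)) > 1e12) {
      gvals <- rep(Inf, nset)
      singular <- TRUE
    } else {
      gvals <- sqrt(pmax(Re(diag(Ginv)) * dG, 0))
    }
    for (col in seq_len(nset))
      maps[[pos[col, 1]]][pos[col, 2], pos[col, 3]] <- gvals[col]
  }
  gv <- unlist(lapply(seq_len(nsl), function(i) {
    g <- maps[[i]]
    if (!is.null(mask)) g <- g[mask[[i]]]
    g
  }))
  gv <- gv[is.finite(gv)]
  out <- list(maps = maps, mb_group = mb_group, method = "analytic",
              R_pe = R_pe, R_ro = R_ro, singular = singular,
              mean_g = if (length(gv)) mean(gv) else NA_real_,
              max_g = if (length(gv)) max(gv) else NA_real_)
  class(out) <- "g_factor_map"
  out
}

#' @export
print.g_factor_map <- function(x, ...) {
  cat(sprintf(
    "g-factor map (%s): %d slice(s), R_pe=%d, R_ro=%d, mean %.3f, max %.3f%s\n",
    x$method, length(x$maps), x$R_pe, x$R_ro, x$mean_g, x$max_g,
    if (isTRUE(x$singular)) " [singular sets present]" else ""))
  invisible(x)
}

# Least-squares (SENSE) unmixing of an aliased multi-coil image set;
# returns per-slice complex images at the true object amplitude (the
# 1/(R_pe*R_ro) fold attenuation of the zero-filled unitary transform is
# compensated).
sense_unmix <- function(aliased_coil_images, coils, mb_group, R_pe, R_ro) {
  N <- coils$matrix
  p <- fold_periods(N, R_pe, R_ro)
  nsl <- length(mb_group)
  nc <- coils$n_coils
  offs <- expand.grid(a = seq_len(R_ro) - 1, b = seq_len(R_pe) - 1)
  out <- lapply(seq_len(nsl), function(i) base::matrix(0 + 0i, N, N))
  for (x0 in seq_len(p["px"])) for (y0 in seq_len(p["py"])) {
    xs <- x0 + offs$a * p["px"]
    ys <- y0 + offs$b * p["py"]
    nset <- nsl * nrow(offs)
    E <- base::matrix(0 + 0i, nc, nset)
    col <- 0L
    pos <- base::matrix(0L, nset, 3)
    for (si in seq_len(nsl)) for (k in seq_len(nrow(offs))) {
      col <- col + 1L
      E[, col] <- vapply(seq_len(nc), function(cc)
        coils$maps[[mb_group[si]]][[cc]][xs[k], ys[k]], 0 + 0i)
      pos[col, ] <- c(si, xs[k], ys[k])
    }
    a <- vapply(seq_len(nc), function(cc)
      aliased_coil_images[[cc]][x0, y0], 0 + 0i)
    s_hat <- tryCatch(qr.solve(E, a) * (R_pe * R_ro), error = function(e)
      rep(NA_complex_, nset))
    for (col in seq_len(nset))
      out[[pos[col, 1]]][pos[col, 2], pos[col, 3]] <- s_hat[col]
  }
  out
}

#' Pseudo-replica (Monte Carlo) g-factor maps
#'
#' Propagates pure-noise replicas through a linear unaliasing
#' reconstruction and estimates g as the per-voxel ratio of accelerated
#' to unaccelerated noise standard deviation, normalised by the square
#' root of the total undersampling.  The default reconstruction is
#' least-squares (SENSE-form) unmixing built from the same coil maps the
#' analytic formula uses, with matched-filter coil combination as the
#' unaccelerated reference.
#'
#' @inheritParams analytic_g_factor
#' @param n_reps number of noise replicas (>= 30; a smaller value is
#'   recorded as a warning flag in the result).
#' @param seed RNG seed.
#' @param noise_sigma per-sample complex noise sd (g is invariant to it).
#' @return a `g_factor_map` (method `"pseudo_replica"`).
#' @export
pseudo_replica_g <- function(coils, mb_group = 1, R_pe = 1, R_ro = 1,
                             n_reps = 100, seed = 1, noise_sigma = 1,
                             mask = NULL) {
  stopifnot(inherits(coils, "mux_coils"))
  N <- coils$matrix
  fold_periods(N, R_pe, R_ro)
  nsl <- length(mb_group)
  nc <- coils$n_coils
  warn <- NULL
  if (n_reps < 30) warn <- "n_reps < 30: g estimates will be unstable"
  set.seed(as.integer(seed))
  R_tot <- R_pe * R_ro
  acq_x <- seq(1, N, by = R_ro)
  acq_y <- seq(1, N, by = R_pe)
  p <- fold_periods(N, R_pe, R_ro)
  offs <- expand.grid(a = seq_len(R_ro) - 1, b = seq_len(R_pe) - 1)
  nset <- nsl * nrow(offs)

  # precompute the least-squares unmixing matrix of every aliased set
  sets <- list()
  si_i <- 0L
  for (x0 in seq_len(p["px"])) for (y0 in seq_len(p["py"])) {
    xs <- x0 + offs$a * p["px"]
    ys <- y0 + offs$b * p["py"]
    E <- base::matrix(0 + 0i, nc, nset)
    col <- 0L
    pos <- base::matrix(0L, nset, 3)
    for (si in seq_len(nsl)) for (k in seq_len(nrow(offs))) {
      col <- col + 1L
      E[, col] <- vapply(seq_len(nc), function(cc)
        coils$maps[[mb_group[si]]][[cc]][xs[k], ys[k]], 0 + 0i)
      pos[col, ] <- c(si, xs[k], ys[k])
    }
    U <- tryCatch(solve(Conj(t(E)) %*% E, Conj(t(E))),
                  error = function(e) NULL)
    si_i <- si_i + 1L
    sets[[si_i]] <- list(x0 = x0, y0 = y0, U = U, pos = pos,
                         ee = Re(colSums(Mod(E)^2)))
  }

  acc <- lapply(seq_len(nsl), function(i) base::matrix(0, N, N))
  acc2 <- lapply(seq_len(nsl), function(i) base::matrix(0, N, N))
  full <- lapply(seq_len(nsl), function(i) base::matrix(0, N, N))
  full2 <- lapply(seq_len(nsl), function(i) base::matrix(0, N, N))
  den_mf <- lapply(seq_len(nsl), function(si)
    Reduce(`+`, lapply(coils$maps[[mb_group[si]]],
                       function(cm) Mod(cm)^2)))
  for (rep in seq_len(n_reps)) {
    # accelerated replica: noise only on the undersampled grid
    noise_img <- lapply(seq_len(nc), function(cc) {
      K <- base::matrix(0 + 0i, N, N)
      K[acq_x, acq_y] <- base::matrix(
        crnorm(length(acq_x) * length(acq_y), noise_sigma),
        length(acq_x), length(acq_y))
      ift2c(K)
    })
    for (st in sets) {
      if (is.null(st$U)) next
      a <- vapply(seq_len(nc), function(cc)
        noise_img[[cc]][st$x0, st$y0], 0 + 0i)
      s_hat <- st$U %*% a
      for (col in seq_len(nrow(st$pos))) {
        si <- st$pos[col, 1]
        v <- Mod(s_hat[col])
        acc[[si]][st$pos[col, 2], st$pos[col, 3]] <-
          acc[[si]][st$pos[col, 2], st$pos[col, 3]] + v
        acc2[[si]][st$pos[col, 2], st$pos[col, 3]] <-
          acc2[[si]][st$pos[col, 2], st$pos[col, 3]] + v^2
      }
    }
    # unaccelerated replica: full noise grid, matched-filter combine
    fnoise <- lapply(seq_len(nc), function(cc)
      ift2c(base::matrix(crnorm(N * N, noise_sigma), N, N)))
    for (si in seq_len(nsl)) {
      num <- 0
      for (cc in seq_len(nc))
        num <- num + Conj(coils$maps[[mb_group[si]]][[cc]]) * fnoise[[cc]]
      v2 <- Mod(num / den_mf[[si]])
      full[[si]] <- full[[si]] + v2
      full2[[si]] <- full2[[si]] + v2^2
    }
  }
  # with the unitary FT convention the accelerated replica carries
  # sigma^2/R noise per voxel, so the std ratio equals g/sqrt(R_total)
  maps <- lapply(seq_len(nsl), function(si) {
    sd_acc <- sqrt(pmax(acc2[[si]] / n_reps - (acc[[si]] / n_reps)^2, 0))
    sd_full <- sqrt(pmax(full2[[si]] / n_reps - (full[[si]] / n_reps)^2, 0))
    sd_acc / pmax(sd_full, .Machine$double.eps) * sqrt(R_tot)
  })
  gv <- unlist(lapply(seq_len(nsl), function(i) {
    g <- maps[[i]]
    if (!is.null(mask)) g <- g[mask[[i]]]
    g
  }))
  gv <- gv[is.finite(gv)]
  out <- list(maps = maps, mb_group = mb_group, method = "pseudo_replica",
              R_pe = R_pe, R_ro = R_ro, n_reps = n_reps, warning = warn,
              singular = FALSE,
              mean_g = if (length(gv)) mean(gv) else NA_real_,
              max_g = if (length(gv)) max(gv) else NA_real_)
  class(out) <- "g_factor_map"
  out
}

#' ROI signal-to-noise estimate
#'
#' Mean signal over a tissue region divided by mean over an air region.
#' @param image magnitude image.
#' @param tissue_mask,air_mask disjoint non-empty logical masks.
#' @return scalar ratio.
#' @export
snr_roi <- function(image, tissue_mask, air_mask) {
  if (!any(tissue_mask) || !any(air_mask))
    stop("masks must be non-empty")
  if (any(tissue_mask & air_mask))
    stop("tissue and air masks must be disjoint")
  mean(image[tissue_mask]) / mean(image[air_mask])
}

#' SNR cost of two-axis k-space undersampling
#'
#' Relative SNR `1 / (g * sqrt(R1 * R2))`: undersampling the k-space by
#' `R1 * R2` reduces SNR by the square root of the total reduction, on
#' top of the coil-geometry penalty g.
#' @param R1,R2 reduction factors (>= 1).
#' @param g g-factor (>= 1).
#' @return relative SNR in (0, 1].
#' @export
undersampling_snr_law <- function(R1, R2, g = 1) {
  if (R1 < 1 || R2 < 1) stop("reduction factors must be >= 1")
  if (any(g < 1)) stop("g must be >= 1")
  1 / (g * sqrt(R1 * R2))
}

#' Residual aliasing of separated slices
#'
#' Per-slice scale-invariant relative L2 error of reconstructed slices
#' against reference slices, plus a leakage matrix: entry `(i, j)` is
#' the magnitude of the component of slice j's reconstruction error
#' lying along reference slice i, relative to the norm of reference
#' slice j.
#' @param recon_slices,truth_slices lists of matrices with matched
#'   geometry.
#' @return list with `rel_error` (vector) and `leakage` (matrix).
#' @export
residual_aliasing <- function(recon_slices, truth_slices) {
  ns <- length(recon_slices)
  if (ns != length(truth_slices))
    stop("slice count mismatch")
  if (!all(dim(recon_slices[[1]]) == dim(truth_slices[[1]])))
    stop("slice geometry mismatch")
  rel_error <- vapply(seq_len(ns), function(j)
    rel_rmse(recon_slices[[j]], truth_slices[[j]]), 0)
  L <- base::matrix(0, ns, ns)
  for (j in seq_len(ns)) {
    tj <- truth_slices[[j]]
    rj <- recon_slices[[j]]
    a <- sum(Conj(rj) * tj) / max(sum(Mod(rj)^2), .Machine$double.eps)
    err <- a * rj - tj
    for (i in seq_len(ns)) {
      ti <- truth_slices[[i]]
      L[i, j] <- Mod(sum(Conj(ti / sqrt(sum(Mod(ti)^2))) * err)) /
        sqrt(sum(Mod(tj)^2))
    }
  }
  list(rel_error = rel_error, leakage = L)
}
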