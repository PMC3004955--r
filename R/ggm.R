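# Gaussian/gamma mixture model (GGM) calibration of z-statistic images.
# Ordinary least-squares z-statistics are miscalibrated when the
# regression residuals are autocorrelated (effective temporal degrees of
# freedom below nominal); fitting a central Gaussian null plus positive
# and negative gamma activation tails to the z histogram, then shifting
# and rescaling so the null has zero mean and unit variance, restores a
# calibrated null regardless of the true DoF.

#' Fit a Gaussian + two-gamma mixture to a z-statistic image
#'
#' Expectation-maximisation fit of three components to the voxelwise z
#' values: a central Gaussian null `N(mu0, sigma0^2)`, a positive gamma
#' on `z - mu0` (activation) and a negative gamma on `mu0 - z`
#' (deactivation), both offset to the null mean.  Initialisation: null
#' moments from the interquartile range, gamma components from the tail
#' mass beyond two initial sigmas.  Gamma components whose
#' responsibility mass vanishes are frozen at negligible weight.
#'
#' @param z numeric vector or array of z values (>= 1000 values
#'   recommended for a stable fit; fewer triggers a warning).
#' @param max_iter EM iteration cap.
#' @param tol convergence tolerance on the mean log-likelihood.
#' @return object of class `ggm_fit`: `mu0`, `sigma0`, `w` (weights:
#'   null, pos, neg), `shape_pos`, `scale_pos`, `shape_neg`,
#'   `scale_neg`, `threshold` (raw-z units; smallest z above the null
#'   mean where the activation density overtakes the null density, or
#'   `Inf` when there is no crossing), `converged`, `loglik`,
#'   `n_iter`.
#' @export
fit_ggm <- function(z, max_iter = 500, tol = 1e-6) {
  z <- as.numeric(z)
  z <- z[is.finite(z)]
  n <- length(z)
  if (n < 50) stop("too few voxels to fit a mixture")
  if (n < 1000)
    warning("fewer than 1000 voxels; mixture fit may be unstable")

  mu0 <- stats::median(z)
  sigma0 <- max(stats::IQR(z) / 1.349, 1e-3)
  shape_p <- shape_n <- 2
  scale_p <- scale_n <- sigma0
  pos_tail <- mean(z > mu0 + 2 * sigma0)
  neg_tail <- mean(z < mu0 - 2 * sigma0)
  # a calibrated Gaussian has 2.3% mass beyond 2 sigma per side
  w <- c(null = 1, pos = max(pos_tail - 0.023, 0.01),
         neg = max(neg_tail - 0.023, 0.01))
  w["null"] <- 1 - w["pos"] - w["neg"]

  dens <- function() {
    d0 <- w["null"] * stats::dnorm(z, mu0, sigma0)
    xp <- z - mu0
    dp <- ifelse(xp > 0,
                 w["pos"] * stats::dgamma(xp, shape = shape_p,
                                          scale = scale_p), 0)
    xn <- mu0 - z
    dn <- ifelse(xn > 0,
                 w["neg"] * stats::dgamma(xn, shape = shape_n,
                                          scale = scale_n), 0)
    D <- cbind(d0, dp, dn)
    # a shape < 1 gamma diverges at its origin; cap so the EM stays finite
    D[!is.finite(D)] <- 1e6
    D
  }
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  active <- c(pos = TRUE, neg = TRUE)
  for (it in seq_len(max_iter)) {
    D <- dens()
    tot <- pmax(rowSums(D), 1e-300)
    ll <- mean(log(tot))
    R <- D / tot
    R[!is.finite(R)] <- 0
    wn <- unname(colMeans(R))
    w <- c(null = wn[1], pos = wn[2], neg = wn[3])
    # the null is by assumption the dominant, central component; keep
    # its weight majority and its width bounded away from collapse
    if (w["null"] < 0.5) {
      shrink <- (1 - 0.5) / (w["pos"] + w["neg"])
      w["pos"] <- w["pos"] * shrink
      w["neg"] <- w["neg"] * shrink
      w["null"] <- 1 - w["pos"] - w["neg"]
    }
    r0 <- R[, 1]
    mu0 <- sum(r0 * z) / sum(r0)
    sigma0 <- sqrt(sum(r0 * (z - mu0)^2) / sum(r0))
    sigma0 <- max(sigma0, 0.05 * stats::sd(z), 1e-3)
    # gamma components by weighted method of moments
    upd_gamma <- function(x, r) {
      sel <- x > 0 & r > 1e-12
      if (sum(r[sel]) < 1e-8 * n) return(NULL)
      m <- sum(r[sel] * x[sel]) / sum(r[sel])
      # keep the activation mode clear of the null core, so gaussian
      # tails are not absorbed into the gamma components
      m <- max(m, 2.5 * sigma0)
      v <- sum(r[sel] * (x[sel] - m)^2) / sum(r[sel])
      v <- max(v, 1e-6)
      list(shape = min(max(m^2 / v, 0.2), 100), scale = max(v / m, 1e-4))
    }
    gp <- upd_gamma(z - mu0, R[, 2])
    if (!is.null(gp)) {
      shape_p <- gp$shape; scale_p <- gp$scale
    } else {
      active["pos"] <- FALSE; w["pos"] <- 1e-8
    }
    gn <- upd_gamma(mu0 - z, R[, 3])
    if (!is.null(gn)) {
      shape_n <- gn$shape; scale_n <- gn$scale
    } else {
      active["neg"] <- FALSE; w["neg"] <- 1e-8
    }
    w <- w / sum(w)
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }

  fit <- list(mu0 = mu0, sigma0 = sigma0, w = w,
              shape_pos = shape_p, scale_pos = scale_p,
              shape_neg = shape_n, scale_neg = scale_n,
              converged = converged, loglik = ll_old, n_iter = it,
              n = n)
  fit$threshold <- ggm_threshold(fit, max(z))
  class(fit) <- "ggm_fit"
  fit
}

# Smallest z > mu0 where the positive-activation density matches the
# null density (probability of 'active' equals probability of
# 'background'); Inf when the activation component never overtakes.
ggm_threshold <- function(fit, zmax) {
  if (fit$w["pos"] <= 1e-6) return(Inf)
  zs <- seq(fit$mu0 + 1e-6, max(zmax, fit$mu0 + 10 * fit$sigma0),
            length.out = 4096)
  d0 <- fit$w["null"] * stats::dnorm(zs, fit$mu0, fit$sigma0)
  dp <- fit$w["pos"] * stats::dgamma(zs - fit$mu0, shape = fit$shape_pos,
                                     scale = fit$scale_pos)
  cross <- which(dp >= d0)
  # ignore any crossing at the immediate left edge of the gamma (shape<1)
  if (!length(cross)) return(Inf)
  runs <- cross[c(TRUE, diff(cross) > 1)]
  cand <- zs[runs[length(runs)]]
  if (cand >= zs[length(zs)] - 1e-9) cand <- zs[runs[1]]
  cand
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf(
    "GGM fit (n=%d): null N(%.3f, %.3f^2) w=%.3f | gamma+ (%.2f, %.2f) w=%.3f | gamma- (%.2f, %.2f) w=%.3f\n",
    x$n, x$mu0, x$sigma0, x$w["null"], x$shape_pos, x$scale_pos,
    x$w["pos"], x$shape_neg, x$scale_neg, x$w["neg"]))
  cat(sprintf("  threshold (raw z) %.3f | %s after %d iter\n", x$threshold,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Mixture-model correction of a z image
#'
#' Shifts and rescales all z values so the fitted null component has
#' zero mean and unit variance: `z_corr = (z - mu0) / sigma0`.  The
#' mixture threshold is carried over to the corrected scale.
#' @param z raw z image (vector or array).
#' @param fit a [fit_ggm()] result; fitted to `z` when missing.
#' @return object of class `zstat_image`: `z_raw`, `z_corr` (same shape
#'   as input), `threshold` (corrected scale), `fit`.
#' @export
correct_z <- function(z, fit = NULL) {
  if (is.null(fit)) fit <- fit_ggm(z)
  zc <- (z - fit$mu0) / fit$sigma0
  out <- list(z_raw = z, z_corr = zc,
              threshold = (fit$threshold - fit$mu0) / fit$sigma0,
              fit = fit)
  class(out) <- "zstat_image"
  out
}

#' Summary metrics of a corrected z image
#'
#' The two principal measures: the peak corrected z value and the sum of
#' all corrected z values above the mixture threshold; plus, at the peak
#' voxel, the parameter estimate (network amplitude) and residual
#' standard deviation as percent of the mean signal, and their ratio
#' (a DoF-free contrast-to-noise measure).
#' @param zimg a [correct_z()] result.
#' @param pe_map,resid_map,mean_map vectors/arrays matching the z image:
#'   regression amplitude, residual sd, and mean signal level.
#' @return list: `peak_z`, `peak_index`, `sum_z_over_threshold`,
#'   `pe_pct`, `resid_pct`, `pe_over_resid`, `threshold`.
#' @export
rsn_metrics <- function(zimg, pe_map = NULL, resid_map = NULL,
                        mean_map = NULL) {
  stopifnot(inherits(zimg, "zstat_image"))
  zc <- as.numeric(zimg$z_corr)
  ipk <- which.max(zc)
  thr <- zimg$threshold
  over <- zc > thr
  out <- list(peak_z = zc[ipk], peak_index = ipk,
              sum_z_over_threshold = if (any(over)) sum(zc[over]) else 0,
              threshold = thr,
              pe_pct = NA_real_, resid_pct = NA_real_,
              pe_over_resid = NA_real_)
  if (!is.null(pe_map) && !is.null(mean_map)) {
    m <- as.numeric(mean_map)[ipk]
    out$pe_pct <- 100 * as.numeric(pe_map)[ipk] / m
    if (!is.null(resid_map)) {
      out$resid_pct <- 100 * as.numeric(resid_map)[ipk] / m
      out$pe_over_resid <- out$pe_pct / out$resid_pct
    }
  }
  out
}
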