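# Shared numerical helpers: centred 2D FFTs, coil combination, error metrics.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circularly shift a matrix along both dimensions
#' @param x matrix
#' @param s length-2 integer shift (positive = towards higher index)
#' @return shifted matrix
#' @keywords internal
circshift2 <- function(x, s) {
  d <- dim(x)
  i <- ((seq_len(d[1]) - 1 - s[1]) %% d[1]) + 1
  j <- ((seq_len(d[2]) - 1 - s[2]) %% d[2]) + 1
  x[i, j, drop = FALSE]
}

fftshift2 <- function(x) circshift2(x, floor(dim(x) / 2))
ifftshift2 <- function(x) circshift2(x, -floor(dim(x) / 2))

#' Centred 2D Fourier transforms
#'
#' `ft2c` maps a centred image to centred k-space (DC at
#' `floor(n/2)+1`); `ift2c` is its inverse.  Unitary scaling so Parseval
#' holds with equal energy on both sides.
#' @param x complex matrix
#' @return complex matrix of the same size
#' @keywords internal
ft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

ift2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

#' Root-sum-of-squares coil combination
#' @param coil_images list of complex matrices, one per coil
#' @return nonnegative real matrix
#' @export
rss_combine <- function(coil_images) {
  stopifnot(length(coil_images) >= 1)
  acc <- 0
  for (im in coil_images) acc <- acc + Mod(im)^2
  sqrt(acc)
}

#' Scale-optimal relative root-mean-square error
#'
#' RMSE between `x` and reference `ref` after the global complex scale of
#' `x` has been fitted by least squares, normalised by `||ref||`.
#' Reconstruction outputs carry an arbitrary global scale, so comparisons
#' against ground truth are made scale-invariantly.
#' @param x,ref numeric or complex arrays of identical size
#' @return nonnegative scalar (fraction of the reference norm)
#' @export
rel_rmse <- function(x, ref) {
  stopifnot(length(x) == length(ref))
  nref <- sqrt(sum(Mod(ref)^2))
  if (nref == 0) return(sqrt(sum(Mod(x)^2)))
  a <- sum(Conj(x) * ref) / max(sum(Mod(x)^2), .Machine$double.eps)
  sqrt(sum(Mod(a * x - ref)^2)) / nref
}

#' Circular complex Gaussian noise
#' @param n number of samples
#' @param sigma standard deviation of the complex sample
#'   (each real/imaginary part has sd `sigma/sqrt(2)`)
#' @return complex vector
#' @keywords internal
crnorm <- function(n, sigma) {
  complex(real = stats::rnorm(n, sd = sigma / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sigma / sqrt(2)))
}
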