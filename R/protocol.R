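# Sequence protocol container and plain-text (key=value) persistence.

#' Describe an M-EPI acquisition protocol
#'
#' Collects every sequence parameter used by the timing model and the
#' k-space simulator: the SIR factor `m` (temporal multiplexing, number of
#' closely spaced excitations whose echoes interleave within each readout
#' period), the multiband factor `n` (spatial multiplexing, slices excited
#' simultaneously per RF pulse), the in-plane parallel-imaging reduction
#' `R_pe`, partial-Fourier fraction, matrix size, receiver bandwidth,
#' timing components and RF settings.
#'
#' @param m SIR factor (>= 1).
#' @param n multiband factor (>= 1).
#' @param R_pe in-plane phase-encode reduction factor (>= 1).
#' @param pf partial-Fourier fraction in (0.5, 1].
#' @param matrix image matrix size (square).
#' @param bw_per_pixel receiver bandwidth per pixel (Hz); the flat-top
#'   readout window per line per image is `1/bw_per_pixel`.
#' @param t_ramp_total gradient ramp plus dead time per echo (s).  Default
#'   0.28 ms, calibrated so the echo-spacing model reproduces typical
#'   production values at 2604 Hz/pixel.
#' @param TE echo time (s).
#' @param TR repetition time (s).
#' @param flip excitation flip angle (degrees).
#' @param n_slices total number of slices for whole-volume coverage.
#' @param t_fatsat fat-saturation pulse duration (s), shared by all `m*n`
#'   images of one shot.
#' @param t_exc,t_refocus RF excitation / refocusing pulse durations (s).
#' @param t_spoil end-of-shot spoiler duration (s).
#' @param sequence_type `"gradient-echo"` or `"spin-echo"`.
#' @param B0 main field strength (T).
#' @param Gs_exc,Gs_refocus slice-select gradient amplitudes (mT/m).  In a
#'   SIR spin echo the refocusing gradient is `m` times weaker so that one
#'   refocusing pulse covers the `m` adjacent slices.
#' @param fov_mm field of view (mm).
#' @return an object of class `mux_protocol` (a validated list).
#' @examples
#' p <- protocol_spec(m = 2, n = 2, R_pe = 2, TR = 0.8, flip = 60)
#' echo_spacing(p)
#' @export
protocol_spec <- function(m = 1L, n = 1L, R_pe = 1L, pf = 1,
                          matrix = 64L, bw_per_pixel = 2604,
                          t_ramp_total = 0.28e-3,
                          TE = 0.040, TR = 2.5, flip = 90,
                          n_slices = 36L, t_fatsat = 13e-3,
                          t_exc = 2.56e-3, t_refocus = 5.12e-3,
                          t_spoil = 1e-3,
                          sequence_type = c("gradient-echo", "spin-echo"),
                          B0 = 3, Gs_exc = 20, Gs_refocus = NULL,
                          fov_mm = 192) {
  sequence_type <- match.arg(sequence_type)
  if (is.null(Gs_refocus)) Gs_refocus <- Gs_exc / m
  spec <- list(m = as.integer(m), n = as.integer(n), R_pe = as.integer(R_pe),
               pf = pf, matrix = as.integer(matrix),
               bw_per_pixel = bw_per_pixel, t_flat = 1 / bw_per_pixel,
               t_ramp_total = t_ramp_total, TE = TE, TR = TR, flip = flip,
               n_slices = as.integer(n_slices), t_fatsat = t_fatsat,
               t_exc = t_exc, t_refocus = t_refocus, t_spoil = t_spoil,
               sequence_type = sequence_type, B0 = B0,
               Gs_exc = Gs_exc, Gs_refocus = Gs_refocus, fov_mm = fov_mm)
  class(spec) <- "mux_protocol"
  validate_protocol(spec)
  spec
}

validate_protocol <- function(spec) {
  stopifnot(inherits(spec, "mux_protocol"))
  with(spec, {
    if (m < 1 || n < 1 || R_pe < 1)
      stop("m, n and R_pe must all be >= 1")
    if (pf <= 0.5 || pf > 1)
      stop("partial-Fourier fraction must lie in (0.5, 1]")
    if (matrix < 8) stop("matrix size too small")
    if (any(c(t_flat, TE, TR, flip) <= 0) || any(c(t_ramp_total, t_fatsat,
        t_exc, t_refocus, t_spoil) < 0))
      stop("all protocol times must be positive (durations nonnegative)")
    if (n_slices < 1) stop("n_slices must be >= 1")
    if (Gs_exc <= 0 || Gs_refocus <= 0) stop("slice gradients must be > 0")
  })
  invisible(spec)
}

#' @export
print.mux_protocol <- function(x, ...) {
  cat(sprintf("M-EPI protocol: %dx%d (SIR x MB), R=%d, pf=%.3g, %dx%d matrix\n",
              x$m, x$n, x$R_pe, x$pf, x$matrix, x$matrix))
  cat(sprintf("  TR %.3g s | TE %.3g ms | flip %g deg | %d slices | %s\n",
              x$TR, 1e3 * x$TE, x$flip, x$n_slices, x$sequence_type))
  cat(sprintf("  echo spacing %.3g ms | train %.3g ms | accel %d-fold\n",
              1e3 * echo_spacing(x), 1e3 * echo_train_duration(x),
              acceleration_factor(x$m, x$n, x$R_pe)))
  invisible(x)
}

#' Read / write a protocol as a key=value text file
#'
#' The on-disk format is one `key = value` pair per line; `#` starts a
#' comment.  Unknown keys are rejected.
#' @param path file path.
#' @param spec a `mux_protocol`.
#' @return `read_protocol` returns a `mux_protocol`; `write_protocol`
#'   returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed protocol line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  allowed <- names(formals(protocol_spec))
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown protocol key(s): ", paste(unknown, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v)) vals[i] else v
  })
  names(args) <- keys
  do.call(protocol_spec, args)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(spec, path) {
  validate_protocol(spec)
  drop <- c("t_flat")  # derived
  keys <- setdiff(names(spec), drop)
  fmt <- vapply(keys, function(k) {
    v <- spec[[k]]
    sprintf("%s = %s", k, if (is.character(v)) v else format(v, digits = 12))
  }, "")
  writeLines(fmt, path)
  invisible(path)
}
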