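# Deterministic arithmetic model of M-EPI sequence timing, acceleration,
# SAR proxy and chemical-shift displacement.

GAMMA_BAR_HZ_PER_T <- 42.577e6   # proton gyromagnetic ratio / 2*pi
FAT_SHIFT_PPM <- 3.35            # default water-fat chemical shift

#' Echo spacing of an M-EPI readout
#'
#' Time per k-space line of a single image.  Each readout period holds the
#' `m` temporally interleaved SIR sub-readouts plus one ramp/dead-time
#' block, so the spacing is `m * t_flat + t_ramp_total`.  Ramp sampling
#' (which shortens the effective dead time) applies only to single-SIR
#' acquisitions and is modelled as a smaller `t_ramp_total`, not at
#' waveform level.
#'
#' @param spec a [protocol_spec()].
#' @return echo spacing in seconds.
#' @export
echo_spacing <- function(spec) {
  validate_protocol(spec)
  spec$m * spec$t_flat + spec$t_ramp_total
}

#' Duration of the EPI echo train
#'
#' `ceil(matrix * pf / R_pe)` acquired phase-encode lines times the echo
#' spacing.  This is the quantity that trades distortion against
#' acceleration: it scales linearly with the SIR factor `m` through the
#' echo spacing and inversely with `R_pe`.
#' @inheritParams echo_spacing
#' @return train duration in seconds.
#' @export
echo_train_duration <- function(spec) {
  n_pe_lines(spec) * echo_spacing(spec)
}

#' Number of acquired phase-encode lines
#' @inheritParams echo_spacing
#' @return integer line count
#' @export
n_pe_lines <- function(spec) {
  validate_protocol(spec)
  as.integer(ceiling(spec$matrix * spec$pf / spec$R_pe))
}

#' Average acquisition time per slice
#'
#' TR divided by the number of slices, reported in milliseconds.
#' @param TR repetition time (s).
#' @param n_slices slice count (>= 1).
#' @param digits rounding for report output (round-half-even); `NULL`
#'   disables rounding.
#' @return time per slice in ms.
#' @examples
#' time_per_slice(2.5, 36)  # 69 ms
#' time_per_slice(0.4, 36)  # 11 ms
#' @export
time_per_slice <- function(TR, n_slices, digits = 0) {
  if (n_slices < 1) stop("n_slices must be >= 1")
  tps <- 1e3 * TR / n_slices
  if (is.null(digits)) tps else round(tps, digits)
}

#' Minimum achievable TR for whole-volume coverage
#'
#' Explicit per-shot decomposition: fat saturation + excitation block +
#' delay filling to TE + echo train + spoiler, times the
#' `ceil(n_slices/(m*n))` shots needed to cover the volume.  The TE-fill
#' delay is the part of TE not already spent reaching the k-space centre
#' line of the train.
#' @inheritParams echo_spacing
#' @return minimum TR in seconds.
#' @export
min_tr <- function(spec) {
  validate_protocol(spec)
  esp <- echo_spacing(spec)
  # lines acquired before the centre of k-space under partial Fourier
  lines_to_centre <- ceiling((spec$pf - 0.5) * spec$matrix / spec$R_pe)
  t_to_centre <- lines_to_centre * esp
  exc_block <- spec$m * spec$t_exc +
    if (spec$sequence_type == "spin-echo") spec$t_refocus else 0
  te_fill <- max(spec$TE - t_to_centre - exc_block / 2, 0)
  shot <- spec$t_fatsat + exc_block + te_fill +
    echo_train_duration(spec) + spec$t_spoil
  ceiling(spec$n_slices / (spec$m * spec$n)) * shot
}

#' Shared fat-saturation overhead per slice
#'
#' One fat-saturation pulse precedes each shot and is shared by all
#' `m * n` images of that shot, so its per-slice cost is `t_fatsat/(m*n)`.
#' @param t_fatsat fat-saturation pulse duration (s or ms; returned in the
#'   same unit).
#' @param m,n SIR and multiband factors.
#' @return overhead per slice, same unit as `t_fatsat`.
#' @examples
#' fatsat_overhead_per_slice(13, 2, 2)  # 3.25 ms
#' @export
fatsat_overhead_per_slice <- function(t_fatsat, m, n) {
  if (m < 1 || n < 1) stop("m and n must be >= 1")
  t_fatsat / (m * n)
}

#' Total scan time
#' @param spec a [protocol_spec()].
#' @param n_volumes number of volumes (fMRI) or diffusion encodings.
#' @return total time in seconds.
#' @examples
#' total_scan_time(protocol_spec(TR = 2), 256) / 60  # ~8.5 min
#' @export
total_scan_time <- function(spec, n_volumes) {
  validate_protocol(spec)
  if (n_volumes < 1) stop("n_volumes must be >= 1")
  spec$TR * n_volumes
}

#' Slice-acceleration product
#' @param m,n,R SIR, multiband and in-plane reduction factors.
#' @return `m * n * R`.
#' @examples
#' acceleration_factor(3, 3, 2)  # 18
#' @export
acceleration_factor <- function(m, n, R) {
  if (any(c(m, n, R) < 1)) stop("all factors must be >= 1")
  m * n * R
}

#' Chemical-shift displacement along the slice axis
#'
#' A species offset by `delta_ppm` is excited/refocused at a position
#' displaced by `D = delta * B0 / Gs`: linear in field strength, inverse
#' in the slice-select gradient.  In a SIR spin echo the refocusing
#' gradient is `m` times weaker than the excitation gradient, so the fat
#' displacement at refocusing is `m` times larger -- for large enough
#' `m * D` the displaced fat band no longer overlaps the excited band and
#' fat is inherently suppressed without saturation pulses.
#'
#' @param delta_ppm chemical shift (ppm); default 3.35 (water-fat).
#' @param B0 field strength (T).
#' @param Gs slice-select gradient amplitude (mT/m).
#' @return displacement in mm.
#' @examples
#' fat_displacement(3.35, 7, 10)   # 2.345 mm
#' @export
fat_displacement <- function(delta_ppm = FAT_SHIFT_PPM, B0 = 3, Gs = 20) {
  if (Gs <= 0) stop("Gs must be > 0 (zero gradient is singular)")
  # delta_ppm*1e-6*B0 [T] / (Gs*1e-3 [T/m]) -> m; *1e3 -> mm
  delta_ppm * B0 / Gs
}

#' Fat resonance offset
#' @inheritParams fat_displacement
#' @return chemical-shift frequency offset in Hz (negative: fat resonates
#'   below water).
#' @export
fat_offset_hz <- function(delta_ppm = FAT_SHIFT_PPM, B0 = 3) {
  -delta_ppm * 1e-6 * GAMMA_BAR_HZ_PER_T * B0
}

#' Relative RF power bookkeeping (SAR proxy)
#'
#' Time-averaged RF power of a protocol relative to a single-band,
#' non-multiplexed reference covering the same slices.  Pulse energies are
#' proportional to pulse duration; a multiband pulse of `n` bands carries
#' `n^2` times the power of its single-band parent (same pulse form and
#' duration).  Per shot the protocol plays one fat-saturation pulse
#' (shared by `m*n` images), `m` multiband excitations, and -- for spin
#' echo -- a single multiband refocusing pulse covering all `m` SIR
#' slices (this is the SIR SAR saving: `1/m` the refocusing-pulse count).
#'
#' The reference protocol runs at `tr_ref` (default: the same TR, i.e. a
#' fixed-TR, fixed-coverage comparison).  Pass `tr_ref = spec$TR * n` to
#' express the "TR reduced correspondingly by the multiband factor"
#' scenario, under which the excitation term grows as `n^2`.
#'
#' @inheritParams echo_spacing
#' @param tr_ref TR of the single-band reference (s).
#' @param e_fatsat,e_exc,e_refocus relative per-pulse energies of the
#'   single-band pulses; defaults proportional to the protocol durations.
#' @return list with per-term relative power (`fatsat`, `excitation`,
#'   `refocus`), `total`, and the raw pulse counts per TR for both
#'   protocols.
#' @export
sar_proxy <- function(spec, tr_ref = NULL,
                      e_fatsat = NULL, e_exc = NULL, e_refocus = NULL) {
  validate_protocol(spec)
  tr_ref <- tr_ref %||% spec$TR
  e_fatsat <- e_fatsat %||% spec$t_fatsat
  e_exc <- e_exc %||% spec$t_exc
  e_refocus <- e_refocus %||% spec$t_refocus
  se <- spec$sequence_type == "spin-echo"

  shots <- ceiling(spec$n_slices / (spec$m * spec$n))
  counts <- list(fatsat = shots, excitation = shots * spec$m,
                 refocus = if (se) shots else 0)
  counts_ref <- list(fatsat = spec$n_slices, excitation = spec$n_slices,
                     refocus = if (se) spec$n_slices else 0)

  pow <- function(count, e, band_sq, tr) count * e * band_sq / tr
  n2 <- spec$n^2
  terms <- list(
    fatsat = pow(counts$fatsat, e_fatsat, 1, spec$TR) /
             pow(counts_ref$fatsat, e_fatsat, 1, tr_ref),
    excitation = pow(counts$excitation, e_exc, n2, spec$TR) /
                 pow(counts_ref$excitation, e_exc, 1, tr_ref),
    refocus = if (se)
        pow(counts$refocus, e_refocus, n2, spec$TR) /
        pow(counts_ref$refocus, e_refocus, 1, tr_ref)
      else NA_real_
  )
  tot_spec <- pow(counts$fatsat, e_fatsat, 1, spec$TR) +
    pow(counts$excitation, e_exc, n2, spec$TR) +
    (if (se) pow(counts$refocus, e_refocus, n2, spec$TR) else 0)
  tot_ref <- pow(counts_ref$fatsat, e_fatsat, 1, tr_ref) +
    pow(counts_ref$excitation, e_exc, 1, tr_ref) +
    (if (se) pow(counts_ref$refocus, e_refocus, 1, tr_ref) else 0)
  c(terms, list(total = tot_spec / tot_ref,
                pulses_per_tr = counts, pulses_per_tr_ref = counts_ref))
}

#' TE offsets of the SIR sub-images
#'
#' Within one shot the `m` SIR excitations are spaced by the excitation
#' block, and their echoes sit at different sub-readout positions, so the
#' effective TE differs between adjacent SIR images.  Informational only;
#' equalising TEs (e.g. with blipped phase-encode pulses between
#' excitations) is not modelled.
#' @inheritParams echo_spacing
#' @return numeric vector of length `m`: TE offset of each SIR image (s)
#'   relative to the first.
#' @export
sir_te_offsets <- function(spec) {
  validate_protocol(spec)
  j <- seq_len(spec$m) - 1
  # excitation spacing plus sub-readout offset within each readout period
  j * spec$t_exc + j * spec$t_flat
}

#' Timing report for a set of protocols
#' @param specs list of [protocol_spec()] objects.
#' @return data.frame, one row per protocol, with the main derived timing
#'   quantities (ms where noted).
#' @export
timing_report <- function(specs) {
  if (inherits(specs, "mux_protocol")) specs <- list(specs)
  rows <- lapply(specs, function(s) {
    data.frame(m = s$m, n = s$n, R_pe = s$R_pe, TR_s = s$TR,
               n_slices = s$n_slices,
               accel = acceleration_factor(s$m, s$n, s$R_pe),
               echo_spacing_ms = round(1e3 * echo_spacing(s), 2),
               train_ms = round(1e3 * echo_train_duration(s), 2),
               min_tr_s = round(min_tr(s), 4),
               time_per_slice_ms = time_per_slice(s$TR, s$n_slices),
               fatsat_per_slice_ms = round(
                 fatsat_overhead_per_slice(1e3 * s$t_fatsat, s$m, s$n), 1))
  })
  do.call(rbind, rows)
}
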