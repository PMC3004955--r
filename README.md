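# muxepi

A desk-scale simulator, reconstructor and analysis toolkit for
**multiplexed echo planar imaging (M-EPI)** — the pulse-sequence family
that combines two forms of slice multiplexing in a single EPI echo
train:

* **temporal multiplexing** (*m*, SIR — simultaneous image refocused):
  *m* closely timed excitations whose echoes interleave within each
  readout period, so every echo carries *m* k-space lines;
* **spatial multiplexing** (*n*, multiband): each RF pulse excites *n*
  widely spaced slices at once, separated afterwards using receive-coil
  sensitivity differences;
* plus in-plane parallel imaging (*R*) and partial-Fourier sampling.

One echo train therefore encodes *m·n* slices instead of one, cutting
whole-brain fMRI TRs from ~2.5 s to ~0.4 s, at the cost of a longer
echo train (distortion, scales with *m*), coil-geometry noise
amplification (g-factor, grows with *n* and *R*), and reduced
steady-state signal at short TR.  This package lets you study all of
those trade-offs quantitatively without a scanner, and reproduces the
statistical machinery used to compare resting-state fMRI protocols at
different TRs.

## What is inside

| Area | Functions |
| --- | --- |
| Digital phantoms & coils | `make_brain_phantom()`, `make_coil_sensitivities()` |
| Sequence timing & physics arithmetic | `protocol_spec()`, `echo_spacing()`, `echo_train_duration()`, `min_tr()`, `time_per_slice()`, `fatsat_overhead_per_slice()`, `total_scan_time()`, `acceleration_factor()`, `fat_displacement()`, `sar_proxy()`, `timing_report()` |
| k-space forward model | `simulate_mux_acquisition()`, `simulate_singleband_calibration()`, `steady_state_signal()`, `ernst_angle()`, `fat_refocused_fraction()`, `simulate_fmri_series()` |
| Reconstruction | `demux_sir()`, `calibrate_mb_kernel()` (7×7 GRAPPA-type slice-separation operator), `apply_mb_separation()`, `calibrate_inplane_kernel()`, `inplane_unalias()`, `partial_fourier_fill()`, `reconstruct()` |
| Quality metrics | `analytic_g_factor()`, `pseudo_replica_g()`, `snr_roi()`, `undersampling_snr_law()`, `residual_aliasing()` |
| Resting-state sensitivity | `make_rsn_truth()`, `generate_rsn_dataset()`, `preprocess_series()`, `concat_group_pca()`, `dual_regression()`, `single_regression()`, `fit_ggm()`, `correct_z()`, `rsn_metrics()`, `predicted_sensitivity_ratio()` |
| I/O and workflows | NIfTI read/write with TR, protocol key=value files, `run_pipeline()`, a `muxepi` CLI (`inst/cli/muxepi.R`) |

The core statistical pieces, in standard notation:

* steady-state (spoiled) signal `S = sin a (1 − E1)/(1 − cos a · E1)`,
  `E1 = exp(−TR/T1)`; the fixed-duration sensitivity prediction is
  `[S_short/S_long]·sqrt(TR_long/TR_short)`;
* multiband slice separation: a least-squares-fitted k-space operator
  mapping 7×7 multi-coil neighbourhoods of the slice-summed data to
  single-slice, single-coil points;
* SENSE-form noise amplification
  `g = sqrt(diag((EᴴE)⁻¹)·diag(EᴴE))` per aliased voxel set, validated
  by pseudo-replica Monte Carlo, and the undersampling law
  `SNR ∝ 1/(g·sqrt(R₁R₂))`;
* slice-axis chemical-shift displacement `D = δ·B₀/Gs`, which with the
  m-times weaker SIR refocusing gradient shifts fat out of the slab;
* dual regression (spatial then temporal multiple regression, with
  unit-variance timecourses so stage-2 coefficients are amplitudes) and
  a Gaussian + two-gamma mixture fit that rescales each z-statistic map
  so its null component has zero mean and unit variance.

## Worked example

```r
library(muxepi)

# the three 10-minute whole-brain fMRI protocols (36 slices, 3 mm)
specs <- list(protocol_spec(m = 1, n = 1, TR = 2.5, flip = 90),
              protocol_spec(m = 2, n = 2, R_pe = 2, TR = 0.8, flip = 60),
              protocol_spec(m = 3, n = 3, R_pe = 2, TR = 0.4, flip = 50))
timing_report(specs)
#>   m n R_pe TR_s n_slices accel echo_spacing_ms train_ms min_tr_s
#> 1 1 1    1  2.5       36     1            0.66    42.50    2.755
#> 2 2 2    2  0.8       36     8            1.05    33.54    0.660
#> 3 3 3    2  0.4       36    18            1.43    45.83    0.323
#>   time_per_slice_ms fatsat_per_slice_ms
#> 1                69                13.0
#> 2                22                 3.2
#> 3                11                 1.4
```

Per-slice acquisition time falls from 69 ms to 11 ms across the family;
the shared fat-saturation pulse costs 13 ms per slice unaccelerated but
only 3.2 ms at 2×2.  The fixed-duration sensitivity prediction:

```r
predicted_sensitivity_ratio(2.5, 90, 0.4, 50, T1 = 1.2)
#> [1] 1.149532     # ~15% higher raw peak z at TR 0.4 s
```

Simulate and invert a 2×2 acquisition (16 coils, 64² matrix):

```r
ph  <- make_brain_phantom(n_slices = 4, matrix = 64, seed = 1)
co  <- make_coil_sensitivities(ph, n_coils = 16, tilt_deg = 15, seed = 1)
sp  <- protocol_spec(m = 2, n = 2, matrix = 64, TR = 0.8, flip = 60)
mux <- simulate_mux_acquisition(ph, co, sp)
mux
#> M-EPI k-space: 16 coils, 64 echoes x 128 samples (m=2, n=2, R=1)
cal <- simulate_singleband_calibration(ph, co, sp)
rec <- reconstruct(mux, calibration = cal)
rec
#> M-EPI reconstruction: 4 slice(s) (m=2 x n=2, R=1)
```

Each of the 64 echoes holds two interleaved sub-readouts (128 samples);
the reconstruction de-interleaves them, separates the two simultaneously
excited slices per sub-readout with the calibrated 7×7 kernel, and
returns all four slices.  With distortion physics switched off the
separated slices agree with single-band references to well under 2%
relative RMSE (see `tests/testthat/test-acceptance.R`).

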