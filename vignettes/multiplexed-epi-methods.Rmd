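---
title: "Simulating and reconstructing multiplexed EPI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing multiplexed EPI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muxepi)
```

# The method in brief

Multiplexed EPI accelerates multi-slice coverage in two independent
ways.  Temporal multiplexing (SIR, factor $m$) plays $m$ closely timed
excitation pulses before one EPI readout train; gradient dephasing
separates their echoes *in time* within each readout period, so every
acquired echo contains $m$ k-space lines belonging to $m$ adjacent
slices.  Spatial multiplexing (multiband, factor $n$) replaces each
excitation pulse with the sum of $n$ frequency-offset pulses, exciting
$n$ widely spaced slices whose signals superimpose and are separated
afterwards using the spatial information in a multi-channel receive
array.  One echo train then encodes $m \times n$ slices; in-plane
parallel imaging ($R$) and partial Fourier shorten the train itself.

`muxepi` implements this as a closed loop: a digital phantom and an
analytic coil array define ground truth; a discrete Fourier forward
model produces the interleaved, aliased, undersampled multi-coil
k-space; the reconstruction inverts it stage by stage; and quality
metrics plus a resting-state analysis pipeline quantify what the
acceleration costs and buys.  Because every input is generated, every
claim in the test suite is checked against a known truth.

# Phantom and coil model

`make_brain_phantom()` builds, per slice, an elliptical head: a scalp
fat ring 2–3 voxels thick (`fat_fraction = 1`), a gray-matter shell, a
white-matter interior and CSF ventricles, with proton density, $T_1$
and $T_2^*$ values in the literature range for 3 T (GM 1.3 s / 60 ms,
WM 0.85 s / 55 ms, CSF 4 s / 200 ms, fat 0.35 s / 70 ms).  A smooth
band-limited random field supplies tissue texture, object phase and an
off-resonance map (default amplitude 30 Hz) with a stronger focal
disturbance mimicking the susceptibility gradient near an air sinus.
Air voxels carry exactly zero signal.

Slice positions span a configurable slab (`z_fov_mm`, default 120 mm):
the $m\cdot n$ slices of one simulated shot are meant to *cover the
head*, so consecutive phantom slices stand for the slice stack and the
multiband partners (every $m$-th slice) end up a fraction $1/n$ of the
slab apart — the "widely spaced" geometry that makes coil separation
well posed.

`make_coil_sensitivities()` places loop elements azimuthally on a
circle outside the head and evaluates an inverse-square falloff
magnitude with a linear spatial phase per coil — smooth by
construction, which is all the reconstruction needs; a Biot–Savart
integration would add realism the kernels never see.  Tilting the ring
about the y-axis (default 15°) gives the elements distinct
z-positions and measurably improves slice encoding.  Every coil is
normalised to the same total energy over the slab (receiver-gain
calibration), so geometry changes alter the *shape*, not the power, of
each channel, and a small random gain/phase jitter is applied per coil.

# Timing arithmetic

All printed protocol numbers come from `protocol_spec()` plus a few
closed forms:

* echo spacing $= m\,t_{\mathrm{flat}} + t_{\mathrm{ramp}}$ with
  $t_{\mathrm{flat}} = 1/\mathrm{bw}$ per pixel.  Default
  $t_{\mathrm{ramp}} = 0.28$ ms, chosen once so that at 2604 Hz/pixel
  the model reproduces typical production spacings (1.05 ms at $m=2$,
  1.44 ms at $m=3$); ramp sampling, which only single-SIR readouts
  support, is modelled as a smaller $t_{\mathrm{ramp}}$ rather than at
  waveform level.
* echo-train duration $= \lceil N_y\,\mathrm{pf}/R\rceil$ lines × echo
  spacing — the quantity that drives distortion, linear in $m$ and
  inverse in $R$.
* minimum TR: per shot, fat-sat + excitation block + a delay filling to
  TE + train + spoiler, times $\lceil N_{\mathrm{slices}}/(mn)\rceil$
  shots.  The decomposition is explicit and each term is configurable,
  since vendor timing tables are not public; derived per-slice times
  are therefore model estimates, while `time_per_slice()` (TR divided
  by slice count) is exact bookkeeping.
* chemical-shift displacement $D = \delta B_0 / G_s$ (mm, with
  $\delta$ in ppm and $G_s$ in mT/m); default $\delta = 3.35$ ppm for
  the water–fat shift.
* `sar_proxy()` does pulse-energy bookkeeping per TR: one shared
  fat-sat pulse per shot, $m$ multiband excitations at $n^2$ relative
  power, and (spin echo) a single multiband refocusing pulse covering
  all $m$ SIR slices.  Relative power is reported against a single-band
  reference at a caller-chosen reference TR: with the TR held fixed the
  refocusing term falls as $1/m$ and the fat-sat term as $1/(mn)$; with
  the TR cut by the multiband factor the excitation term grows as
  $n^2$.  It is a bookkeeping proxy, not a W/kg model.

# Forward model

`simulate_mux_acquisition()` computes, per acquired phase-encode line
and SIR slot, the Fourier line of the coil-weighted slice composite:
per-voxel steady-state amplitude $S = \sin\alpha\,(1-E_1)/(1-\cos\alpha
E_1)$; off-resonance phase $e^{2\pi i\,\Delta f\,t}$ accrued at the
line's acquisition time (gradient echo adds the TE phase); optional
$T_2^*$ decay; the fat resonance offset applied to fat voxels (so the
scalp ring displaces along the phase-encode axis in the image); and, in
spin-echo mode, a fat amplitude factor from the slab-overlap model
described below.  Even echoes are time-reversed (EPI readout polarity),
which flips both the sample order and the SIR slot order; the
de-interleaver undoes this deterministically.  Noise is i.i.d. circular
complex Gaussian per coil with identity coil covariance — no measured
covariance exists for a synthetic array, and every noise-sensitive
metric is either covariance-free ($g$ with $\Psi = I$) or ratio-based.

The simulation is a *discrete-object* Fourier model: k-space is the DFT
of the voxelised phantom.  Reconstruction therefore operates under an
inverse crime — acceptable here because what is being validated is
parameter and structure recovery (separation error, distortion scaling,
noise propagation), not absolute image quality, and noise injection
breaks exact inversion where it matters.

The SIR fat-suppression mechanism is modelled geometrically:
excitation selects a fat band displaced by $D$; the $m$-times weaker
refocusing gradient selects a band displaced by $mD$ and $m$ slices
wide; only the overlap refocuses.  `fat_refocused_fraction()` returns
that overlap for a slice at the slab centre — 1 for conventional spin
echo, 0 once $mD$ clears the slab.

# Reconstruction

The pipeline mirrors the acquisition in reverse: `demux_sir()` (an
exact bijection, tested bit-for-bit with noise), multiband separation,
in-plane GRAPPA, partial-Fourier completion, centred 2D inverse FT and
root-sum-of-squares coil combination.

The multiband separation operator maps $7\times7$ multi-coil k-space
neighbourhoods of the *slice-summed* calibration data to single-slice,
single-coil centre points, fitted by least squares over many
overlapping regions.  Three numerical choices matter:

* **Boundary handling is periodic.**  The k-space of a discrete object
  is exactly periodic, so the coil modulation acts as a circular
  convolution; zero-padding the edges breaks the large cancelling
  weights in the fitted kernel and inflates edge errors by an order of
  magnitude.  Zero-padding remains available as an option.
* **Calibration uses every position**, with the same wrap padding used
  at application time, so fit and application are consistent and the
  fit residual is an honest prediction of application error.
* **Regularisation** is Tikhonov, relative to the mean squared column
  norm, solved by QR of the augmented system (never the normal
  equations).  The default $\lambda = 10^{-10}$ favours accuracy on
  noiseless calibration — it reproduces the identity mapping in the
  degenerate single-slice case to $<10^{-6}$ — and can be raised for
  noisy calibration data, trading bias for noise gain.

When the phase-encode axis is undersampled, the separation kernel is
calibrated and applied on the acquired-line subgrid (the compact ky
lattice), and a standard GRAPPA kernel (4 source lines × 5 readout
taps × all coils, per offset) then fills the missing lines per slice.
Partial Fourier is zero-filled by default; a conjugate-symmetry mode
recovers real-valued objects exactly except the unmappable most
negative frequency row/column.  Slice separation quality is assessed
against single-band reconstructions of the same slices under the same
physics — with off-resonance enabled the per-line phase evolution makes
the composite-to-slice mapping non-convolutional and a shift-invariant
kernel cannot be exact, so the error-budget tests isolate coil-encoding
separation by switching distortion physics off; distortion itself is
tested separately (the phase-encode shift of an off-resonant point
scales as $m$ and $1/R$ to within 5%).

# Noise metrics

`analytic_g_factor()` evaluates the SENSE-form
$g = \sqrt{[(E^{\mathsf H}E)^{-1}]_{ss}\,[E^{\mathsf H}E]_{ss}}$ per
aliased voxel set (slices × phase-encode folds × optional readout
folds); rank-deficient sets are reported as infinite with a flag.
`pseudo_replica_g()` validates it by propagating pure-noise replicas
through the corresponding least-squares unmixing; with the package's
unitary FT convention the accelerated replica carries $\sigma^2/R$
noise per voxel, so $g$ equals the noise-std ratio times $\sqrt{R}$.
One hundred replicas put the per-voxel Monte-Carlo error near 7% and
the mean-$g$ error near 1%.  The two-axis undersampling law
$\mathrm{SNR} \propto 1/(g\sqrt{R_1R_2})$ is verified end to end by
measuring replica SNR of undersampled versus fully sampled
reconstructions.

# Resting-state sensitivity pipeline

`make_rsn_truth()` defines the synthetic study: Gaussian-blob networks
(default 5, peak amplitude 1% of mean signal) with unit-variance
timecourses band-limited below 0.1 Hz; cardiac (~1 Hz, vessel-like
central weighting) and respiratory (~0.3 Hz, global weighting)
confounds at 1% amplitude; thermal noise of constant absolute standard
deviation (default 20 on a fully relaxed mean of 1000), so image SNR
tracks the steady-state signal of each protocol.  Confounds are
narrowband oscillators with a Brownian phase walk (default
1 rad/$\sqrt{\mathrm s}$), giving them the few-second coherence time of
real physiology; everything is generated on a 20 Hz grid and sampled at
each protocol's TR, so aliasing arises naturally (a 1 Hz cardiac
process sampled at TR 2.5 s folds to 0.2 Hz).  Each slice is acquired
at its own offset within the TR: the data contain slice-shifted
confound phases while any single regressor is sampled at the volume
reference time.  At TR 2.5 s the slice spread covers most of a
respiratory cycle and decorrelates the confound from its regressor; at
TR 0.4 s it does not — this sampling geometry, not a tuning constant,
is what makes confound regression more effective at short TR in the
package's experiments.

The analysis follows the standard group pipeline: discrete-cosine
highpass of full width 200 s (components slower than 5 mHz projected
out, mean preserved), per-volume Gaussian smoothing of 5 mm FWHM with
edge-renormalised kernels, per-dataset PCA reduction with
variance-equalised temporal concatenation (`concat_group_pca()`), dual
regression (spatial stage, unit-variance timecourse normalisation,
temporal stage yielding amplitude, residual and OLS z maps) and the
one-regressor-at-a-time variant.  ICA itself is deliberately not
reimplemented: the pipeline accepts ground-truth maps, user-supplied
map files, or the PCA output passed through any external unmixing.

The mixture-model z calibration fits a central Gaussian null plus
positive and negative gamma tails by EM (weighted method of moments for
the gammas, 500-iteration cap, $10^{-6}$ log-likelihood tolerance) and
rescales the image so the null has zero mean and unit variance; the
reporting threshold is the density crossing where a voxel is equally
likely active or background (infinite when no activation component
survives, in which case the suprathreshold sum is zero).  Three
constraints keep the fit stable on realistic maps: gamma means are kept
at least $2.5\sigma_0$ from the null mean (otherwise the gammas absorb
Gaussian tails and bias $\sigma_0$ low by several percent), the null
weight is kept at or above one half, and $\sigma_0$ is floored at 5% of
the sample standard deviation (preventing outright collapse on heavily
smoothed maps).  Across an AR(1) residual sweep ($\rho$ = 0–0.6, where
raw OLS z widens to sd ≈ 1.23) the corrected null recovers mean
0 ± 0.05 and sd 1 ± 0.05.

## Study sizes and what the experiments show

The TR-comparison experiment uses a 20×20×10 voxel grid, 5 networks,
and the three 10-minute protocols TR 2.5 s/90°, 0.8 s/60°, 0.4 s/50°
(the latter two near the Ernst angle for $T_1 \approx 1.2$ s); the
amplitude-recovery check uses 50 independent realisations on a
12×12×4 grid.  These sizes are the smallest at which the mixture fit is
stable and Monte-Carlo error is well below the tested effects.  Three
findings mirror the expected structure: single-regression corrected
peak z is approximately TR-invariant (measured ratios ≈ 1.1–1.2 versus
the Bloch prediction of ≈ 1.15); per-volume residuals as a percent of
mean signal are substantially higher at short TR; and the *remaining*
confound variance fraction after adding confound regressors — measured
against a matched confound-free control run, because raw residual
variances across TRs are dominated by the mean-signal scaling — falls
steeply with TR (≈ 0.5 at 2.5 s to ≈ 0.16 at 0.4 s).

# What the synthetic data do not show

The generators emulate the *structure* of the problem, not a scanner:
no motion, no RF transmit inhomogeneity, no gradient nonlinearity or
ramp-sampling waveforms, no Nyquist ghost calibration beyond the
deterministic polarity flip, no measured coil covariance, and
elliptical phantoms rather than anatomy.  Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave as
the theory predicts under controlled conditions — not that any given
in-vivo dataset would yield the same numbers.  In-vivo values
(absolute SNR, measured g-factors, empirical peak-z ratios) are outside
the package's scope.  Off-resonance *correction* is likewise out of
scope: the simulator produces distortion and the metrics quantify it,
but no field-map unwarping is attempted.

# Degenerate inputs and tie-breaks

Zero-filled partial Fourier and $R = 1$ unaliasing are exact
identities; a single-slice "group" reduces the separation operator to
an identity mapping; empty suprathreshold sets yield a zero sum rather
than an error; rank-deficient encoding matrices yield flagged infinite
g rather than crashes; collinear regression designs and degenerate
(constant) regressors are rejected with diagnostics.  Ties at the z
peak between near-equal neighbours are resolved by `which.max` order;
the amplitude metrics are evaluated at that voxel.
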