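Package: muxepi
Title: Simulation and Reconstruction of Multiplexed (SIR x Multiband) Echo
    Planar Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale simulator and reconstruction toolkit for multiplexed
    echo planar imaging (M-EPI), the combination of temporal multiplexing
    (simultaneous image refocused, SIR, factor m) and spatial multiplexing
    (multiband RF excitation, factor n) with in-plane parallel imaging
    (factor R).  Provides digital brain phantoms and analytic receive-coil
    sensitivity maps; an EPI k-space forward model with steady-state signal
    scaling, off-resonance, chemical shift, T2* decay and complex noise;
    reconstruction by SIR de-interleaving, GRAPPA-type multiband slice
    separation with a 7x7 k-space kernel, in-plane GRAPPA unaliasing and
    partial-Fourier completion; sequence timing, SAR-proxy and
    fat-displacement arithmetic; g-factor and pseudo-replica SNR analysis;
    and a resting-state fMRI sensitivity pipeline (group PCA concatenation,
    dual and single regression, Gaussian/gamma mixture-model z-statistic
    calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    RNifti,
    jsonlite,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
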