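---
title: "Incoherent SIM: forward model, reconstruction and metrology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incoherent SIM: forward model, reconstruction and metrology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incosim)
```

This vignette documents the mathematical model behind `incosim`, the
reasoning behind its parameter defaults, and its known limitations.

## 1. Optical model

Both the excitation and the emission path are modeled as ideal,
aberration-free incoherent imaging systems. The radial OTF is the
autocorrelation of a circular pupil ("chat" function),

$$H(\rho) = \frac{2}{\pi}\left(\arccos\rho - \rho\sqrt{1-\rho^2}\right),
\qquad \rho = \nu / \nu_c, \qquad \nu_c = \frac{2\,\mathrm{NA}}{\lambda},$$

implemented in `incoherent_otf()`. The default configuration
(`optical_config()`) is a 100x / 1.3 NA oil objective, 460 nm
excitation, 515 nm emission, 6.5 µm camera pixels (65 nm in the sample
plane): excitation cutoff 5.652 cycles/µm, emission cutoff 5.049
cycles/µm.

The exact chat function, not a Gaussian surrogate, is load-bearing. The
illumination pattern here is an *image of the SLM* formed with
spatially incoherent LED light, so the pattern contrast in the sample
plane is attenuated by exactly $H(k/\nu_c^{ex})$. At the default
operating point ($k = 0.85\,\nu_c^{ex}$) only 6.8% of the contrast
survives; a Gaussian OTF would overestimate this several-fold.
`pattern_contrast_sweep()` measures the transfer through the actual
projection pipeline and reproduces `incoherent_otf()` to machine
precision, while the coherent (interference) reference curve is
constant — the quantitative form of the design trade-off between an
inexpensive incoherent pattern projector and an interferometric one.

## 2. SLM pattern engine

Patterns are binary line gratings rasterized on the SLM pixel grid with
a strict pixel-centre rule (LCOS pixels are binary; no anti-aliasing):
with 0-based pixel coordinates, the position along the pattern normal is
$u = c\sin\alpha + r\cos\alpha$ and a pixel is on iff
$\mathrm{frac}(u/p - i/n) < d$, with period $p$, phase index $i$, phase
count $n$ and duty $d$. With $d = 1/n$ the per-orientation phase windows
partition the period: every pixel is lit in exactly one phase, so the
summed illumination is perfectly homogeneous
(`homogeneity_residual()` is exactly 0) and each orientation delivers
the same mean dose (mark-to-area ratio, `mar_uniformity()`).

Presets:

* `minimal9` — 0/60/120 degrees, 3 phases (duty 1/3): the minimal
  near-isotropic 2D SIM set.
* `bio12` — 0/60/120 degrees, 4 phases (duty 1/4). On a 4-pixel period
  each phase mask is an exact lattice translate of the others, so every
  frame has the same DC. This matters for square-law sectioning (see
  section 5): duty 1/3 of a 4-pixel period is *not* representable, and
  its masks have per-phase mark-to-area ratios 0.5/0.25/0.25.
* `fixed14` — 0/45/90/135 degrees with 4+3+4+3 phases. Diagonal
  orientations use the nearest lattice-representable period
  ($m\sqrt2/2$ pixels, integer $m$), and their duty cannot match the
  axis-aligned one exactly; the documented tolerance on per-orientation
  mean MAR is 0.1.

### Why a 5.2 µm SLM pixel default?

Two design constraints are satisfied simultaneously. First,
*commensurability*: 52 nm (SLM, sample plane) and 65 nm (camera) stand
in ratio 4:5, so a 320x320 SLM region maps onto exactly 256x256 camera
pixels over a common 16.64 µm field, and band-limited resampling between
the grids is exact. Second, *operating frequency*: an integer 4-pixel
period — the smallest DC-balanced binary period with 4 phases — lands at
4.81 cycles/µm = 0.85 of the excitation cutoff, in the demanding
high-frequency band, while staying below the emission cutoff
(0.95 $\nu_c^{em}$) so the pattern remains detectable in the raw frames.
Non-integer periods rasterize with strong phase jitter and satellite
harmonics; integer periods keep the phase stepping digitally exact.

## 3. Forward simulation

For each pattern: `project_pattern()` applies the excitation OTF on the
SLM grid and Fourier-crops to the camera grid (DC preserved exactly);
the illumination multiplies the fluorophore density; the product is
blurred by the emission OTF; an optional background plane at defocus
$z$ is blurred additionally by a Gaussian of width
$\sigma = z\,\mathrm{NA}/n_{oil}$ and sees a correspondingly attenuated
pattern (modulation falls as $e^{-2\pi^2\sigma^2 k^2}$ — at 1.6 µm
defocus the pattern is numerically gone). Frames are scaled so the
noise-free widefield peak equals `peak_photons`, then Poisson shot noise
and Gaussian read noise are applied. All randomness flows through
explicit seeds; identical seeds give bit-identical stacks.

Simplifications: 2D only (single focal plane plus one background
plane), no aberrations, no polarization physics (the LCOS is an ideal
binary amplitude mask), no fluorophore photophysics, linear camera.

## 4. Super-resolution reconstruction

Per orientation with phases $\phi_i$, each frame's spectrum is the
mixture $F_i = S_0 + S_+ e^{i\phi_i} + S_- e^{-i\phi_i}$;
`separate_bands()` solves this per pixel (exactly for 3 phases, least
squares beyond). The side bands are moved to their true frequencies by
real-space phase ramps on a 2x zero-padded grid, weighted against the
widefield band in their OTF overlap (complex regression, capturing
modulation depth and residual phase), and all bands are recombined with
a generalized Wiener filter

$$\hat S(\nu) = \frac{\sum_b \bar c_b\,O_b(\nu)\, D_b(\nu)}
{\sum_b |c_b|^2 O_b(\nu)^2 + w^2}, \qquad w = 0.05,$$

followed by a triangular apodization to the extended passband
$k + \nu_c^{em}$. Because a pattern is only measurable if $k$ lies
inside the detection passband, the radius never exceeds
$2\nu_c^{em}$ — the two-fold limit of linear SIM; `reconstruct_sr_sim()`
refuses inadmissible pattern frequencies.

### Pattern parameter estimation

Reconstruction quality hinges on the pattern frequency and phases. The
estimator (`estimate_pattern_parameters()`) uses two ideas:

1. **Correlation images.** The DFT of $w\cdot(F_i - w)$ (with $w$ the
   widefield image) at frequency $k$ is the Fourier cross-correlation of
   frame and widefield, which concentrates the pattern peak and makes
   the recovered phase independent of the random object spectrum.
2. **Anchored phases.** The SLM shifts patterns by whole sub-period
   pixel steps, so the phase *increments* within an orientation are
   digitally exact; only a global offset and the frequency are unknown.
   The estimator forms the coherent average
   $\sum_i C_i(k)\,\overline{a_i}$ with anchors
   $a_i = e^{i(\phi_i - \phi_1)}$ from the nominal steps. This cancels
   the conjugate band and the beat satellites of oblique binary rasters
   (at 60/120 degrees the rasterized grating carries satellites with
   roughly half the fundamental amplitude), which otherwise bias
   single-frame phase estimates by tens of degrees.

The frequency is refined by a nested grid search on the anchored
power; significance requires both a peak-to-ring power ratio >= 4 and a
phase coherence $|\sum_i z_i \bar a_i|^2 / (n \sum_i |z_i|^2)$ >= 0.7.
An unmodulated stack can reach a moderate value on one of the two
statistics (the refinement search maximizes over a window), but not on
both. Estimation needs a structured field; for very sparse scenes (for
example a two-bead sample) reconstruct with
`recon_params(phase_source = "metadata")`.

## 5. Optical sectioning

`reconstruct_os_sim()` implements square-law detection: the root of the
mean squared pairwise frame difference, pooled over all phase pairs and
orientations. Defocused light is unmodulated — identical across phases —
and cancels; in-focus structure survives. Two practical points:

* **Equal DC per phase is required.** Any per-frame DC difference
  (unequal mask duty) is read as modulation of *everything*, including
  the background. Use repertoires whose duty is pixel-representable
  (`bio12`).
* **Noise does not cancel.** Under Poisson statistics
  $E[(F_i-F_j)^2] = (\mu_i-\mu_j)^2 + \mu_i + \mu_j + 2\sigma_r^2$, so
  the raw square law has a noise floor proportional to local intensity:
  bright defocused regions leak through. The default
  (`bias_correction = TRUE`) subtracts the expected noise term per pair
  (using the read noise recorded in the stack metadata), clamps the
  pooled sum at zero and then takes the root. The correction is skipped
  automatically for noise-free stacks.

`sectioning_experiment()` quantifies the rejection on a two-plane
phantom with in-focus structure on the left and identical structure
1.6 µm out of focus on the right: the defocused half's share of image
energy drops from 0.48 (widefield) to 0.037 (OS-SIM) at the default
photon budget — a ratio of 0.076. The budget (1e6 peak photons) is
chosen so the residual shot-noise floor of the estimator sits well below
the rejected background; at 1e4 the floor, not the optics, would
dominate the measurement.

## 6. Metrology

* `fit_gaussian_fwhm()` / `mean_fwhm_over_beads()`: isotropic 2D
  Gaussian fits (Levenberg–Marquardt) around given bead centres; FWHM
  $= 2\sqrt{2\ln 2}\,\sigma$. Values are reported raw — a 100 nm bead
  inflates the apparent PSF width slightly, and no bead-size
  deconvolution is applied. Failed fits are excluded and listed.
* `pair_resolved()`: intensity profile through two centres; resolved iff
  two local maxima flank a minimum at least 10% below the lower maximum
  (a Rayleigh-like dip criterion).
* `radial_spectrum_support()`: largest radius at which the azimuthally
  averaged log-power spectrum exceeds a percentile noise floor by a
  fixed margin — a scene-independent check that a reconstruction really
  carries energy beyond the widefield cutoff.

With the defaults, 20 simulated beads measure ~196 nm FWHM in widefield
and ~131 nm after SR-SIM (`bead_resolution_experiment()`, and
`scripts/acceptance.R` for a from-scratch run); a 200 nm pair is
unresolved in widefield (dip 0) and clearly resolved after
reconstruction (dip 0.75).

## 7. Synchronization

Ferroelectric LCOS pixels must be DC balanced: every displayed state is
followed by its inverse for an equal duration, and the LED must be
blanked during the refresh and the inverted display so the camera only
integrates the intended pattern. `build_timing()` emits integer-µs
event tables (camera exposure, normal display, LED-on with a guard
margin, refresh, inverted display); `validate_timing()` re-checks
non-overlap, DC balance, LED containment/blanking and pattern coverage
as data rather than trusting construction. DC balancing costs photons:
`illumination_duty()` is bounded below 1/2.

## 8. Known limitations

* The model is 2D; axial structure is reduced to one defocused plane,
  and 3D SIM is out of scope.
* Oblique binary rasters carry satellite harmonics; their per-mask duty
  can deviate from the axis-aligned one (tolerance documented per
  preset). The anchored estimator is robust to this, but per-frame
  unanchored phase estimation would not be.
* Parameter estimation requires a structured field and >= 3 phases per
  orientation; sparse scenes must fall back to metadata phases.
* Pattern contrast measurements are exact by construction (projection
  is a linear Fourier filter); they validate the model wiring, not an
  independent physical measurement.
* The square-law bias correction uses the recorded noise model; stacks
  from other sources need `read_sigma` set correctly in their sidecar,
  or `bias_correction = FALSE`.
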