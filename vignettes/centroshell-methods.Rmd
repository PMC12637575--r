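---
title: "Methods: synthetic centromere imaging and ring morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic centromere imaging and ring morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `centroshell`. Nothing here reports an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

# The generative model

## Structures

Centromeric foci are modelled as one of two density classes, rasterized on
a supersampled grid (3× per axis), convolved with the PSF there, and
point-sampled back onto the acquisition grid:

* **Shells** are semi-enclosed equatorial bands: a Gaussian tube of radial
  sigma `shell_thickness / 2.3548` around the equatorial circle of the
  stated diameter, with the axial tube width multiplied by
  `axial_extent_scale` (default 1.3) so axial views appear slightly oblong.
  The *diameter* is the peak-to-peak distance of the density annulus — the
  quantity the morphometry estimates. A fully closed spherical shell was
  rejected during development: under a 360 nm axial PSF the out-of-plane
  poles fill the lateral midplane, and the fine-grid convolution oracle
  shows the midplane profile of a closed 191–227 nm shell is *unimodal* —
  no ring would ever be observed. Semi-enclosed bands reproduce the
  characteristic bimodal lateral profiles at all four preset sizes.
* **Puncta** are point emitters (trilinear sub-voxel splat), so a rendered
  punctum reproduces the PSF itself — the basis for the PSF-fidelity tests.

Structure mass is normalized so that total integrated intensity equals the
`amplitude` (photon units); rendering is therefore exactly linear in
amplitude, which the intensity-factor recoveries rely on.

## The PSF

`imaging_spec()` supports two lateral models:

* `"sim"` (generator default): a radially symmetric flat optical transfer
  function with a 25% raised-cosine edge taper, cutoff calibrated so the
  real-space PSF has the stated FWHM (calibration constant
  `fc × FWHM = 0.79952`, solved on a fine grid). This is the essential
  feature of a structured-illumination reconstruction: the ring frequency
  of a 191 nm structure (≈ 1/191 cycles/nm) is passed at near-full
  contrast, whereas a Gaussian of the same 125 nm FWHM attenuates it to
  ≈ 0.22 — with a Gaussian lateral PSF no generator geometry can make
  191 nm rings observable, let alone measurable to ±15 nm. Negative
  reconstruction ringing is clipped at zero, as reconstruction software
  does.
* `"gaussian"`: separable Gaussian with sigma `FWHM/2.3548` per axis; used
  by the degradation/restoration module (whose kernels are Gaussian by
  construction) and by the widefield preset.

The axial PSF is Gaussian in both models (default 360 nm, the midpoint of
the 340–380 nm axial band of 3D-SIM).

Noise follows the camera model
`Poisson((I + background) × photon_scale)/photon_scale + N(0, read_noise²)`,
clamped at zero. The default amplitude targets a blurred shell peak of
≈ 240 intensity units over background 10 with read noise 2, i.e. peak
SNR ≈ 15. Ground-truth randomness (positions, kinds, diameters,
amplitudes) is drawn *before* any rendering or noise: Poisson sampling
consumes a data-dependent amount of the RNG stream, and pre-drawing keeps
two conditions generated at the same seed paired structure-for-structure.

## Condition presets

| preset | diameter (nm) | intensity × | ring prob. | DNA cavity |
|--------|---------------|------------|------------|------------|
| cenpa  | 191 ± 30 | 1.00 | 1.00 | 0.4 |
| cenpc  | 227 ± 33 | 1.00 | 1.00 | 0.4 |
| cenpo  | 267 ± 43 | 1.00 | 1.00 | 0.4 |
| cenpt  | 278 ± 42 | 1.00 | 1.00 | 0.4 |
| control| 191 ± 30 | 1.00 | 0.90 | 0.4 |
| plk1i  | 191 ± 30 | 0.50 | 0.05 | 1.0 |
| p221a  | 191 ± 30 | 1.64 | 0.90 | 0.4 |
| dhjurp | 278 ± 42 | 1.00 | 0.10 | 1.0 |

Diameters are truncated-normal with a floor at
`shell_thickness + one pixel` so every drawn shell is geometrically a
shell. The DNA channel is a lognormal random field (Gaussian-smoothed
white noise, 150 nm correlation length, log-sd 0.35) carved
multiplicatively inside each shell: factor `dna_cavity_fraction` for
radii up to the annulus peak, ramping linearly back to 1 across one shell
thickness — so chromatin density starts to fall at the ring's outer
diameter and is lowest in the cavity.

The default minimum centre-to-centre separation is 700 nm (950 nm for the
widefield intensity assay), keeping each structure's outer background box
free of its neighbours.

# Morphometry

## Ring diameter

`measure_ring_diameter()` takes linescans at 36 orientations (5° steps,
probe 800 nm, width 1 pixel, bilinear sampling), finds the highest strict
local maximum on each side of the centroid, refines both by 3-point
parabolic interpolation, and reports the separation at the orientation
that maximizes it (the "longest axis"). Sub-pixel refinement removes most
of the one-pixel quantization bias; it can be disabled to mimic
integer-pixel readout.

Two opposing biases matter. Blurring pulls annulus peaks inward by
roughly `sigma_eff²/R` (a 191 nm band reads ≈ 180 nm noiseless under the
SIM OTF; a 278 nm band ≈ 262 nm), while the resolvability selection
(below) removes the smallest rings from the measured set, pulling the
small-preset mean back up. At the default SNR the measured means across
seeds are ≈ 192–202 / 217–229 / 254–258 / 258–262 nm for truth
191 / 227 / 267 / 278: accurate for the three smaller presets, and
≈ 16 nm low for the largest, where the curvature bias is uncompensated.
Because the reference diameters are themselves peak-to-peak readings of
blurred images, a generator whose annulus truth equals those readings
necessarily under-reads at the large end — a limitation surfaced by a
failing check in the acceptance suite rather than hidden.

## Classification

`classify_structure()` computes a mean radial profile (24 angular spokes,
0.5-pixel radial steps) on the best-focus plane (the z slice maximizing
the 9×9 inner-box sum). A structure is a *punctum* if the radial maximum
sits within 1.5 pixels of the centre, a *ring* if the off-centre peak has
central dip ratio `I(0)/I(peak) ≤ 0.9` and ≥ 75% angular coverage at half
peak, otherwise *unresolved*. The dip threshold is calibrated on the
generator: at default SNR roughly 30% of 191 nm-preset shells are
physically unresolvable (their blurred radial profile peaks at the
centre), and a stricter threshold (e.g. 0.7) both depresses the ring-call
rate and inflates measured mean diameters by ≈ +25 nm through size
selection. With 0.9 the classifier agrees with generator truth on > 90%
of resolvable structures while leaving puncta calls untouched (punctum
discrimination rests on the peak-radius criterion, not the dip).

## Intensity and comparisons

`corrected_spot_intensity()` implements the dual-box estimator on
maximum-intensity projections: `inner − (outer − inner) × 81/88` for the
9/13 defaults. It cancels any uniform offset exactly and is linear.
Condition comparisons normalize to the control mean and use Student's
unpaired t-test (Welch via `var_equal = FALSE`).

The intensity assay uses the `widefield_imaging()` preset (250/600 nm
Gaussian PSF, 65 nm camera pixel, 200 nm z step) — the modality such
kinetochore-intensity measurements are made with. The choice is not
cosmetic: at 65 nm pixels the 9×9 box spans 585 nm and captures rings and
puncta with equal efficiency, so a condition that converts rings to puncta
(e.g. `plk1i`) reads out its true amplitude factor. At SIM resolution and
40 nm pixels the same boxes capture the two shapes differently and a true
−50% reads as ≈ −60%.

# Isotropic resolution enhancement

The protocol: (1) trilinear resample to a 40 nm isotropic grid (output
length per axis `round(n × voxel / target)`, which keeps an
already-isotropic volume bit-identical); (2) degrade — a 1 px Gaussian z
blur (sidelobe suppression), a 2.4 px Gaussian x blur, and ×3 x
decimation/linear re-upsampling, matching what a restorer is trained
against; (3) for each of six angles about y (0–150° in 30° steps), restore
along x and rotate back; (4) keep, at each spatial frequency, the complex
coefficient of largest magnitude across angles; (5) inverse transform and
take the magnitude.

Numerical decisions, each forced by a failure mode observed during
development:

* **Exact Fourier rotations.** For the linear Wiener restorer,
  rotate → filter-along-x → rotate-back equals multiplying the spectrum by
  the 1D filter response at `f·u(θ)`, `u(θ) = (sin θ, 0, cos θ)`. The
  per-frequency maximum then reduces to the maximum of per-angle filter
  responses. Explicit bilinear rotations leave interpolation residuals
  that the inverse filter amplifies 10⁴–10⁶×; the Fourier path has none.
  A spatial path (bilinear, per-angle clamping) remains for nonlinear and
  external restorers.
* **Per-angle matched kernels.** `fusion_for_imaging()` derives the blur
  actually present along the rotated x direction,
  `sqrt(fz² sin²θ + fx² cos²θ)`, from the axial/lateral PSF, the
  degradation blurs, and the resampling smear (a triangle kernel of
  variance `step²/12` per linear resampling step, ≈ `2.3548·step/√6`
  FWHM). A single fixed kernel `sqrt(axial² − lateral²)` over-deconvolves
  at oblique angles (ringing) and under-deconvolves at 90° (the z-blur of
  the degradation is not in it), capping axial recovery near 144 nm.
* **Band limits.** Beyond the x-decimation Nyquist (1/240 cycles/nm at the
  defaults) and the original z-sampling Nyquist the degraded volume
  contains only resampling replicas; restoration rolls off there
  (cosine taper from 80% of the cap) instead of amplifying them.
* **Regularization.** The Wiener floor defaults to 1e-12 in
  `fusion_for_imaging()` — appropriate for noiseless synthetic volumes
  where the only perturbations are at float precision; for noisy data use
  1e-3-ish. The degradation blurs are applied through their exact analytic
  transfer functions (circular FFT) so the restorer's kernel model matches
  the degradation identically; a discrete spatial kernel's transfer
  function deviates at high frequency for ~1 px sigmas, and an inverse
  filter amplifies exactly that deviation.

On noiseless 110/360 nm beads rendered on a 40 nm isotropic grid, the full
protocol restores the axial FWHM to ≈ 106 nm (Gaussian fit, 10 beads).
From a 125 nm z-step instead, any linear restorer is sampling-limited to
≈ 150 nm axial: there is no information beyond the original z Nyquist.
Note the per-frequency maximum is mildly aggressive by construction — on
an already-isotropic input the protocol over-sharpens the axial direction
by up to ~20% rather than acting as an identity.

The x-degradation at its defaults yields a bead x-FWHM of ≈ 283 nm
(125 ⊕ 226 ⊕ resampling), which does not reach the 340–380 nm native
axial band; matching that band would need an x blur of ≈ 3.5 px. The
recipe is used as stated; the discrepancy is surfaced by a failing check
in the acceptance suite rather than hidden.

Training-pair bookkeeping (`make_training_pairs()`) crops input/target
patches at shared seeded locations from the globally degraded views, so a
patch pair is exactly a crop of `degrade()`'s output; the validation split
is `round(fraction × n)`. Neural training hyperparameters are carried as
passthrough metadata for an external plug-in and are never interpreted.

# What the generator does and does not emulate

It emulates: diffraction-limited anisotropic imaging with a SIM-like
lateral OTF, shot + read noise band-limited to the OTF support (a
reconstruction cannot carry out-of-band noise; white post-noise volumes
would overstate rim-peak jitter), realistic structure sizes/densities and
per-structure amplitude variation (lognormal, sd 0.2), a textured
chromatin channel with cavity clearing, and condition effects expressed as
amplitude factors and ring probabilities.

It does not emulate: structured-illumination image *formation*
(illumination patterns, reconstruction artifacts beyond negativity
clipping), chromatin polymer structure, irregular/lobed ring shapes,
labelling stochasticity, or spatially varying background. Passing tests
therefore demonstrate that the measurement code recovers known truth under
a faithful noise/blur model — not that it is robust to every artifact of
real reconstructions.

# Problem sizes

The test suite and acceptance script use 10 nuclei × 15 structures per
marker preset (150 structures), 75 spots per condition for intensity
comparisons, 10 beads for the restoration benchmark, and 100 training
patches — sizes chosen to match the sampling frames the measurements are
designed for while keeping a full run in the minutes range on one CPU.
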