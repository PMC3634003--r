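---
title: "Mapping retinal vessel permeability from fluorescein angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping retinal vessel permeability from fluorescein angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reticad)
```

## The problem and the model

Fluorescein angiography records retinal fluorescence for roughly ten
minutes after an intravenous dye bolus. Where the inner blood–retinal
barrier is intact, tissue fluorescence rises with the arterial bolus
and then declines as dye washes out; where the barrier leaks, dye
accumulates in tissue and fluorescence keeps rising. `reticad` turns
this qualitative observation into a per-pixel statistic in three steps.

**Normalization.** Absolute fluorescence depends on dose, camera gain
and media opacity, so each frame is divided by the mean intensity of a
manually selected region over the major arteries leaving the optic
disc — the arterial input function (AIF). Normalized intensity
$\tilde I(x,t) = I(x,t)/\mathrm{AIF}(t)$ is unitless and invariant to
any global intensity scale, which the test-suite checks as an exact
property.

**Slope.** A straight line is fitted (ordinary least squares) to
$\tilde I(x,t)$ against time in seconds over the *late phase* of the
study. A single linear coefficient is deliberately simple: it needs no
kinetic model beyond "accumulation vs washout", is robust at the ~40
late-phase time points available, and is the quantity thresholded and
displayed. Under a Patlak-type view, tissue signal
$\approx v\,\mathrm{AIF}(t) + k \int_0^t \mathrm{AIF}$, so the
normalized late-phase trend is approximately $k$ when the AIF is nearly
flat — the slope is an effective permeability rate in units of
normalized intensity per second.

**Threshold and map.** Slope values from a healthy cohort are pooled as
a *mean cumulative histogram*: each subject's empirical CDF is evaluated
on a common grid and the CDFs are averaged unweighted, so subjects with
different usable-pixel counts contribute equally. The smallest slope at
which the mean CDF reaches 99.5 % becomes the pathological threshold;
maps render sub-threshold pixels blue and supra-threshold pixels on a
linear yellow-to-red ramp (red pinned at the 99.9th percentile of
supra-threshold slopes; the ramp endpoints are a display choice, not a
measurement).

## Pipeline parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_corr` (frame exclusion) | 0.5 | Pearson r | correlation to the pixel-wise *median* frame; the median is robust to the large intensity swing across angiographic phases. Pre-injection frames are nearly featureless and are expected to fail this gate. |
| LOG filter `size`, `sigma` | 8 px, 1.4 px | pixels | edge enhancement before shift estimation; kernel is mean-subtracted so a constant image yields an exactly zero response. |
| `upsample` | 100 | – | sub-pixel refinement to 0.01 px via a matrix-multiply DFT restricted to a 1.5 px neighborhood of the coarse peak. |
| `band_sigma` | 0.15 (registration), 0.25 (bare estimator) | cycles/px | Gaussian weight on the whitened cross-power spectrum; suppresses noise-dominated high-frequency phase. |
| `refine` | 1 | passes | re-estimation of each frame against the average of registered frames (see below). |
| `fit_start_s` | 120 | s | start of the late phase. The acquisition protocol switches to its slow rate at 90 s; by 120 s the transit peak has passed and the kinetics are in their slow decline/accumulation regime. |
| `min_points` | 4 | frames | fewer late-phase points make a slope meaningless. |
| AIF floor | 10 % of AIF max | – | frames with AIF below the floor (pre-dye, transit onset) are dropped before normalization; dividing by a near-zero AIF is unstable. |
| `percentile` | 0.995 | – | healthy quantile defining "pathological". Exposed because the source convention is ambiguous between 99.5 % and its complement misprint. |
| border margin | 8 | px | Fourier resampling wraps content circularly at frame edges; the margin is excluded from calibration and scoring. |

## Registration design

Shift estimation is *phase correlation* in the strict sense: the
cross-power spectrum is normalized to unit modulus before the inverse
transform. Plain cross-correlation, tried first, showed a systematic
bias during the transit phase — arteries, veins and tissue brighten
asynchronously, and re-weighting of spatially offset structures drags an
amplitude-weighted peak. Whitening makes the estimate depend on phase
only and removed most of that bias. Two further choices matter:

* a Hann taper on the filtered frames before the FFT (boundary effects
  of the reflect-padded filter otherwise corrupt the whitened phase);
* a Gaussian spectral weight (`band_sigma`), because whitened phase at
  frequencies with little scene energy is pure noise.

The sequence is chained outward from the reference frame (the frame
most correlated with the series mean), estimating each frame against
its inward already-registered neighbor and composing cumulatively,
with excluded frames bypassed. A pure chain accumulates per-link error
as a random walk — on the phantom this alone exceeds a 0.05 px budget —
so a refinement pass then re-estimates every frame against the *average
of the registered frames* and re-anchors the reference at exactly
(0, 0). Registering to the averaged image is standard practice for
drift removal and the averaged registered image is also the natural
backdrop for ROI drawing. Shifts are applied to the original
(unfiltered) frames by Fourier phase shift, which exactly inverts the
estimation model; the unpaired Nyquist bin is realified so real images
map to real images. Rotation and scaling are not modeled.

## What the phantom emulates — and what it does not

`generate_phantom()` renders a 128×128, 73-frame sequence following the
two-phase clinical protocol (20 frames/min for the first 90 s, then
5 frames/min to 600 s). Its stated world:

* **AIF**: gamma-variate bolus (arrival 10 s, peak 28 s, amplitude 150
  camera units) plus a recirculation plateau (35 % of peak, 30 s rise)
  decaying with a 2500 s systemic time constant — fluorescein's plasma
  half-life is on the order of half an hour.
* **Kinetic classes**: arteries trace the AIF; veins trace it delayed
  by 3 s; tissue follows `0.35 · AIF · exp(-(t - t0)/350)` plus a leak
  term `k · ∫AIF` (cumulative trapezoid), so zero-`k` tissue washes out
  and leaky tissue accumulates with late-phase normalized slope ≈ `k`;
  the optic disc is a bright blob with a physiological leak rate of
  1.5e-3 s⁻¹, which is why it is excluded from all statistics.
* **Anatomy**: two arcades with two branches each plus second-order
  daughter branches, Gaussian cross-sections, paired veins on
  alternating sides; a static two-scale background texture
  (choroidal-scale σ 4 px and nerve-fiber-scale σ 1.8 px); a sensor
  pedestal of 10 camera units.
* **Degradations**: per-frame random-walk translation (0.5 px/frame
  steps) and additive Gaussian sensor noise (2 camera units), drawn
  after the motion, clipped at zero.

One rendering subtlety is deliberate: all band-limited content is moved
by an exact Fourier shift (for such content this *is* the correct
physics of sampling a translated scene), but the sharp-edged disc is
re-rendered analytically at its true position each frame, with a
pixel-coverage rim and a 0.7 px optical blur. Fourier-shifting a hard
edge instead would (a) hand the estimator an artificially perfect
broadband anchor — its aliased ringing follows the phase-shift model
exactly, a simulation/estimator collusion — and (b) imprint a
cos²(πs) Nyquist flicker on the registered stack that corrupts
late-phase slopes even under oracle alignment. Both effects were
observed and are the reason for the analytic disc.

The phantom does **not** emulate: optics beyond the single disc blur
(no PSF, no vignetting), photobleaching, rotation or deformable motion,
pathology-specific lesion morphology (microaneurysms, neovascular
fronds), or inter-subject anatomical variability. A green test
therefore establishes that the *algorithms* recover a stated world with
known kinetics under translation-plus-noise degradation — not that the
pipeline is clinically validated.

Ground-truth rasters live in the phantom's canonical (zero-shift)
frame; a registered stack lives in its reference frame's coordinates,
so `phantom_masks_at()` re-renders the truth masks at the reference
drift before any truth-based comparison.

## Numerical choices and degenerate inputs

* **Float TIFF round trips** are bit-exact at 32-bit precision; invalid
  slope pixels serialize as NaN to keep "not fitted" distinct from a
  zero slope.
* **Polygon rasterization** sets a pixel when its center is inside the
  polygon (even-odd rule) or on an edge, so boundary pixels are always
  included; an axis-aligned 10×10 square rasterizes to exactly 100
  pixels.
* **Ties**: the reference-frame search breaks ties toward the lowest
  index; `derive_threshold` returns the *smallest* grid value whose
  mean CDF reaches the percentile.
* **Degeneracies**: constant frames are rejected by disc detection and
  shift estimation; a single-category rating table returns an explicit
  degenerate (`NA`) kappa; bootstrap replicates with degenerate kappas
  are dropped, with a warning when they exceed 10 %; a McNemar test
  with no discordant pairs returns p = 1; an eye whose disc centroid
  lies within 2 % of the midline is labelled `"ambiguous"` rather than
  guessed.
* **Exact tests**: the one-tailed McNemar test is an exact binomial
  tail — with ~21 subjects and few discordant pairs the asymptotic χ²
  is unreliable; the corrected χ² form is available as an option.
* **Seeds**: every stochastic routine (phantom, cohort, bootstrap)
  requires an explicit seed and restores the caller's RNG state;
  per-subject streams derive from the master seed, so a cohort is a
  pure function of its seed.

## Known limitations

* Translation-only registration: torsional or pulsatile deformation
  would leave residuals the phantom does not model.
* The slope threshold is a single healthy-cohort quantile; no
  age/gender stratification.
* The per-axis 95th-percentile registration recovery on the default
  phantom sits near 0.03–0.05 px; individual frames during dye transit
  can reach ~0.1 px because the scene genuinely changes between
  frames — an irreducible feature of angiographic registration, not of
  the implementation.
* Reported clinical agreement statistics (κ ≈ 0.8–0.86, sensitivity
  0.974) depend on private rater tables and image data; the package
  implements the estimators and validates them against oracles, but
  does not — and cannot — reproduce those specific values.
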