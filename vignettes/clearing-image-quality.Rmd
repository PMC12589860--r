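---
title: "Quantifying confocal image quality in tissue-clearing experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying confocal image quality in tissue-clearing experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clariquant)
```

## The problem

Tissue-clearing protocols (CUBIC and relatives) aim to make thick tissue
optically transparent so that labeled microvasculature can be imaged by
confocal microscopy well below the cut surface. Protocol choices —
delipidation time and reagent concentration, autofluorescence quenchers,
label chemistry — trade off signal strength, background suppression, and
depth penetration. `clariquant` quantifies those trade-offs directly from
z-stacks with three families of metrics:

1. **Paired bright/dark SNR** per optical section, an automated
   local-contrast measure;
2. **Depth-intensity profiles** and a **percent relative intensity**
   summary of depth penetration;
3. **Niblack/DICE colocalization** of two label channels.

A condition-comparison layer (ANOVA + Tukey HSD) turns per-sample metrics
into protocol-level conclusions, and a synthetic vascular-phantom
generator provides ground-truthed test data.

## The analysis volume

Acquisitions are square optical sections (typically 1024 × 1024 pixels at
0.4 µm/pixel) at a fixed axial step (5 µm for clearing assessment). Each
slice is center-cropped — by default to 512 × 512 — to avoid vignetting at
the field edges; the crop is an exact sub-array with origin
`floor((extent − size)/2)` on each axis (the floor rule fixes behavior for
odd remainders, which the centered-crop convention leaves open). Because
vibratome sectioning leaves a rough surface, the analyst designates the
**surface slice** (imaging depth 0); depths are
`(slice − surface) × z_step`, so 150 µm at 5-µm spacing spans 31 analyzed
slices. `suggest_surface_slice()` automates a suggestion (first slice with
Niblack-foreground coverage in all four quadrants) but is advisory only:
the designation is a judgment about tissue, and the manual choice remains
the primary interface. Slice indices are 1-based throughout, following R
convention; all depth arithmetic is index-origin invariant.

Intensities are carried at native scale without normalization. Every
metric below is invariant to multiplicative gain — SNR is a log ratio,
percent relative intensity a ratio, Niblack masks compare a pixel to an
affine-equivariant local threshold — so rescaling would only discard
acquisition metadata.

## Paired bright/dark SNR

For each slice, up to `n_regions = 15` **bright regions** are selected
greedily: the brightest 5 × 5-pixel window, then repeatedly the brightest
remaining window at least 75 pixels (center-to-center) from all accepted
ones, which spreads the sample across distinct vessels. For each bright
region a **dark region** is the 20 × 20 window with the lowest intensity
standard deviation inside a 61 × 61 search box centered on the bright
center — a proxy for quiet extravascular tissue. The pair SNR is

$$\mathrm{SNR}_i = \log_{10}\!\frac{\mu_\text{bright}}{\sigma_\text{dark}},$$

and the slice SNR is the arithmetic mean over pairs.

Numerical conventions, fixed project-wide:

* **Population σ** (divide by *N*) for all window standard deviations —
  conventional for image windows; the same estimator is used in the
  brute-force oracles the tests compare against.
* **Euclidean** center distance for the spacing constraint (`>=`
  comparison); Chebyshev is available as an option.
* **Ties** in window mean or sd break toward the smallest (row, col) in
  row-major order, making results deterministic. A flat-topped blob
  therefore yields its top-left-most interior window, not its centroid.
* Even-sized windows are addressed by their top-left corner; their center
  is `top_left + (w−1)/2` (half-integer). Search boxes are clamped at
  image borders; the dark window itself is never shrunk.
* **σ = 0 windows**: the log ratio is undefined, so the search retries
  restricted to positive-σ windows; if none exists in the box the pair is
  dropped (with a warning) and the slice mean uses the remaining pairs.
  Real tissue never produces this; uniform synthetic backgrounds can.
* Fewer than 15 feasible bright regions is a warning, not an error — the
  fixed 15 presumes dense vasculature.

The spacing constraint is re-verified on every `slice_snr()` call, not
only in tests. Windowed statistics run on integral images (summed-area
tables), with window variances clamped at zero to absorb floating-point
cancellation; exhaustive per-window loops in the test suite confirm exact
positional agreement on random slices.

## Depth profiles and percent relative intensity

The per-slice mean intensity of the cropped region, indexed by depth,
forms the depth profile. Depth penetration is summarized as

$$\text{percent relative intensity} =
  100 \times \frac{\bar I(\text{reference depth})}{\bar I(0)},$$

with reference depth 150 µm by default. When a batch contains shallower
stacks, the deepest depth common to all of them (typically 105 µm) is the
sensible reference and is caller-suppliable; `run_analyze()` falls back
to the deepest acquired depth with a note in the report. Values above
100 % are legal — a rough surface slice can be dimmer than tissue just
below it. Means are computed on raw values with no background
subtraction, and reference depths must coincide with acquired slices: the
package never interpolates between sections.

`fit_attenuation()` recovers a decay parameter from a measured profile by
least squares: the slope of log-intensity against depth (sign-flipped)
under the exponential model, or the raw intensity slope under the linear
model.

## Niblack thresholding and DICE

Vessel masks use the Niblack local rule with offset coefficient −1: a
pixel is foreground iff its intensity strictly exceeds
$\mu_w - \sigma_w$ of the 55 × 55 window centered on it. The strict
inequality makes perfectly uniform regions background, suppressing flat
tissue. Borders are handled by symmetric (edge-including) reflection
padding so masks cover the full slice — a full-size mask is needed for
honest DICE pixel counts. Two properties worth knowing:

* The mask commutes with multiplicative gain *and* with additive offsets
  (both window statistics transform with the data); both are tested.
* Around a sharp step edge the rule marks a band on *both* sides: the
  high side always, and the low side wherever the high fraction *p* of
  the window satisfies $p < 1/2$ (there $\mu_w - \sigma_w < 0$). Niblack
  with k = −1 is a local-contrast detector, not an absolute segmenter —
  on noise-dominated flat regions it marks most pixels, which is why the
  surface-suggestion heuristic built on it is advisory and is validated
  on low-noise phantoms.

Two-channel colocalization binarizes both channels with identical
parameters and reports

$$\mathrm{DICE} = \frac{2\,|A \cap B|}{|A| + |B|},$$

flagged as undefined (not 0/0) when both masks are empty, alongside the
per-channel slice SNR.

## Theoretical resolution

From acquisition settings the package reports the Rayleigh lateral
resolution $0.61\,\lambda/\mathrm{NA}$ and the wide-field axial resolution
$2 n \lambda / \mathrm{NA}^2$, using the excitation wavelength (561 nm,
NA 0.75, n 1.52 gives 456 nm and 3032 nm after rounding — both the raw
and rounded values are carried so downstream tools never re-round), plus
a boolean Nyquist check that the z-step is below the axial resolution.

## The synthetic phantom generator

`generate_phantom()` emulates what the analysis assumes about real
stacks: bright tubular vessels over a darker heterogeneous background,
monotone depth decay, optional quencher suppression, and acquisition
noise. Construction order matters and is part of the contract — noiseless
image first, then per-slice attenuation, then noise — and the truth
records pre-noise vessel membership and per-slice noiseless means.

Default conditions (chosen once as a realistic clearing assessment and
held fixed):

| parameter | default | rationale |
|---|---|---|
| shape | 31 × 512 × 512 | 150 µm at 5-µm steps on the standard crop |
| pixel size | 0.4 µm | standard lateral sampling |
| vessel radius | 3.55 ± 1 µm | capillary caliber (≈7 µm diameter) |
| vessel count / length | 40, 150 ± 50 µm | dense myocardial capillary bed |
| orientation | in-plane azimuths, 10° tilt sd | capillaries follow fibers, sections cut near-parallel |
| vessel intensity / background | 150 / 20 | strong label over autofluorescence (8-bit-like scale) |
| texture sd | 5 | tissue heterogeneity visible but below label contrast |
| attenuation | exponential, 0.004/µm | ≈55 % relative intensity at 150 µm, mid-range for cleared tissue |
| noise | gaussian, sd 0.4 | 2 % of background, a clean confocal acquisition |

Implementation choices:

* Tubes are rasterized by physical distance-to-segment per voxel with a
  **1-voxel linear edge falloff** — aliasing-free edges keep the 5 × 5
  bright-window statistics stable. Radii are physical (µm), so tubes keep
  caliber under anisotropic voxels. Vessels leaving the volume are
  clipped with a warning.
* The background texture field is smoothed white noise, **centered to
  exactly zero mean per slice** before rescaling, so texture never shifts
  a slice's mean intensity; residual slice-mean variation on noiseless
  phantoms comes only from vessel-edge compositing against the random
  background.
* The quencher is a multiplicative $e^{-q\,\text{depth}}$ stacked on the
  base attenuation — residual dye absorbs light along the path, so its
  effect compounds with depth and leaves the surface untouched.
* Gaussian noise is additive with clipping at 0; Poisson noise draws
  photon-like counts with a gain (intensity units per count). No
  physically based scattering, PSF convolution, or branching topology is
  modeled.
* The RNG seed is mandatory; the same spec is bit-reproducible.

**Validation phantoms.** Depth-penetration checks (attenuation-rate
recovery, the closed-form percent-relative-intensity comparison) use
*z-penetrating columnar vessels* at seeded lateral positions: every slice
then has an identical noiseless cross-section, the unattenuated per-slice
mean is depth-constant, and the measured profile isolates the attenuation
model exactly. Randomly oriented networks add per-slice vessel-sampling
variability that is real but is not attenuation, so they are used for
structural tests (truth-mask consistency, determinism) rather than for
parameter recovery. This is also what passing tests do and do not show
about real data: the phantom validates the *measurement chain*, not the
optics — real stacks add scattering, PSF anisotropy, spherical
aberration, and vessel-network structure the generator does not attempt.

## Condition-comparison statistics

Each sample contributes one value per metric (inter-sample variance;
within-slice pair spread is not modeled). `anova_conditions()` fits
main-effects-only linear models — one factor, or two factors without
interaction — with type-II sums of squares for unbalanced data (declared
in the output; the experimental designs this serves are balanced, where
the types coincide). `tukey_hsd_conditions()` gives studentized-range
pairwise comparisons at α = 0.05; with two levels it reduces to the
pooled t-test, which the tests verify. Normality and homoscedasticity are
not tested — typical group sizes (2–4) cannot support such tests — and
the report carries a caveat line instead. The degenerate all-identical
case (zero residual variance) is resolved explicitly: identical groups
get p = 1, distinct ones p → 0, rather than NaN.

Calibration is checked by simulation: under a seeded null (three groups
of four from one normal distribution, 1000 replicates) the one-way ANOVA
rejects at α = 0.05 at the nominal rate within sampling tolerance.

## Problem sizes and runtime choices

The test suite exercises the full geometry logic on reduced stacks
(64–128 px laterally, windows scaled to 3/6/15 px with 10-px spacing) so
that exhaustive brute-force oracles stay affordable; full 512 × 512
slices with the standard 5/20/61/75-px windows run through the same code
path and are used in the acceptance script's standard-size phantom.
Attenuation recovery uses 20 phantoms of 31 × 96 × 96; the statistics
calibration uses 1000 replicates.

## Known limitations

* Niblack k = −1 on pure-noise regions marks most pixels foreground; the
  surface heuristic is therefore advisory (see above).
* No channel registration, spectral unmixing, or bleed-through
  correction; colocalization assumes co-registered channels.
* No interpolation between slices; metrics exist only at acquired depths.
* The phantom's depth decay is exponential or linear; abrupt decay
  regimes (e.g., a rapid drop over a narrow depth band, as poorly
  cleared tissue can show) are not modeled — fitting those profiles with
  the exponential model will average the regimes.
* Vendor microscope formats are not read; convert to multi-page grayscale
  TIFF upstream.
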