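---
title: "Quantifying wound angiogenesis from large-scale optoacoustic microscopy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wound angiogenesis from large-scale optoacoustic microscopy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Label-free optoacoustic (photoacoustic) microscopy images the skin
microvasculature through the optical absorption of hemoglobin: nanosecond
laser pulses focused to a few micrometres generate broadband ultrasound
wherever blood absorbs, and a confocally aligned detector records one
depth-resolved trace (an *A-scan*) per pulse. Scanned over centimetre-scale
fields of view, this yields volumetric maps of perfused vessels in healing
skin wounds, at capillary resolution, repeatedly in the same animal and
without any contrast agent.

`woundvasc` implements the downstream quantification for such data:

1. **Preprocessing** — band-pass filtering of A-scans, per-pulse energy
   correction, regridding of the scan trajectory to a regular voxel grid,
   maximum-amplitude projection (MAP) with the depth index of the maximum,
   CLAHE contrast compression and relative-depth color encoding.
2. **Resolution estimation** — a robust logistic fit to an edge-target scan
   (edge-spread function) and the FWHM of its derivative (line-spread
   function).
3. **Layer separation** — splitting each volume into the superficial
   capillary plexus and the deeper cutaneous vessels along a fitted, curved
   separation surface.
4. **Vessel morphometrics** — binarization, skeletonization, branch
   decomposition, and per-segment length, diameter, orientation, tortuosity
   and angular alignment toward the wound center.
5. **Wound-level aggregation** — healing/re-vascularization scores with
   logistic kinetics, 400 µm heat maps over a 6 mm extent, and radial
   profiles of the vessel parameters.
6. **A phantom generator** — seeded, ground-truthed synthetic scenes that
   stand in for the (unavailable) animal data and back every quantitative
   claim in the test suite.

## The synthetic world

No imaging data are distributed with the package, so validation rests on a
generator whose statistical structure mirrors the biology the pipeline
assumes. Its defaults are fixed once, from the regimes reported for dorsal
mouse skin, and the test suite treats them as the stated world:

* Two vascular layers separated by a smooth, non-planar surface: tortuous
  superficial capillaries (diameters 10–30 µm, turning rate ≈ 0.65°/µm)
  riding 10–40 µm above the surface, and nearly straight deep vessels
  (35–50 µm) situated 60–140 µm below it. The surface is a gentle quadratic
  in scaled lateral coordinates (mean depth ≈ 450 µm, ±150 µm across a
  7 mm field), emulating the residual tilt and curvature of mechanically
  flattened skin.
* Vessels are rendered as Gaussian-profile tubes, amplitude
  $\exp(-d^2/2\sigma^2)$ with $\sigma = r/2$, composited by per-voxel
  maximum. Band-limited optoacoustic signals do not produce hard cylinder
  edges; the smooth profile exercises diameter estimation realistically. A
  voxel "belongs" to a vessel out to the $1/e^2$ amplitude level, which by
  construction sits exactly at the nominal radius.
* Capillary tortuosity comes from a random-walk heading with von
  Mises-distributed turning increments; the concentration is calibrated so
  the expected absolute turning per unit length equals the configured
  °/µm target. This gives a single tortuosity knob that the morphometric
  stage must recover.
* Wound time series: a circular full-thickness wound (5 mm diameter) whose
  *avascular area* is $(1 - c(t))$ of the initial area, with $c(t)$ a
  logistic closure (defaults $k = 1.2\,\mathrm{day}^{-1}$, $t_0 = 5.5$ dpw,
  placing the peak re-vascularization rate at 5.5 dpw) or explicit
  per-timepoint targets. While closure is incomplete, a ring of tortuous,
  ~1.5× dilated sprouts occupies the annulus just outside the avascular
  margin; the revascularized annulus between the current margin and the
  original border fills with radially aligned, much straighter vessels whose
  mean alignment and turning rate follow per-timepoint schedules (defaults:
  alignment 0.1→0.9 and tortuosity 1.2→0.35 °/µm from 5 to 13 dpw).
* Vessel placement is stratified (jittered lattices / polar grids) rather
  than Poisson: capillary beds are space-filling, and Poisson placement
  leaves void sizes that no perfused tissue shows, which would make the
  vascularized-area measurement ill-posed rather than test it.
* Noise is additive Gaussian on the amplitude (default σ = 0.02 of the unit
  vessel amplitude); an optional Gaussian PSF (7.5 µm lateral / 35 µm axial
  FWHM) emulates the instrument blur. No speckle or depth-dependent
  fluence model is included.

What a green test on this world does **not** establish: robustness to
motion artifacts, eschar shadowing, depth-dependent sensitivity loss,
vessels below the resolution limit, or the manual judgment embedded in
marking initial wound outlines on photographs. Those belong to the
instrument and the experimenter, not to this package.

```{r}
library(woundvasc)
res <- run_pipeline(run_config(out_dir = "run1", seed = 7,
                               wound = wound_series_config(seed = 7)))
res$scores          # healing / re-vascularization per dpw
res$curve           # fitted logistic kinetics
head(res$tables[[1]])  # per-segment morphometrics at the first timepoint
```

## Preprocessing choices

**Zero-phase band-pass.** The acquisition band-pass (2–50 MHz, third-order
Butterworth) is applied as the squared Butterworth magnitude response in the
frequency domain — the exact equivalent of forward–backward filtering. A
causal filter would delay the envelope and bias the depth index by several
samples; zero phase preserves depth localization. DC is removed exactly.

**Energy correction** divides each A-scan by its recorded relative pulse
energy, inverting the acquisition scaling exactly; corrected energies are
set to one. (Renormalizing by the realized mean energy instead would leave a
systematic residual of order jitter/√n and break the round-trip identity the
tests assert.)

**Regridding** assigns pulses to nearest grid nodes, averages multiple hits
and fills empty nodes by iterative nearest-neighbor dilation, flagged in an
attribute; >5% empty warns, >50% is an error. The default sinusoidal
trajectory density (4 pulses per node) covers every node, so the fill path
is exercised only by degraded trajectories.

**MAP and depth index** operate on the absolute amplitude; ties take the
first (shallowest) maximum, consistent with relative-depth display where
superficial structures dominate. Zero depth is the shallowest above-threshold
signal (10% of the map maximum by default).

**CLAHE** uses 8×8 tiles with a clip limit of 0.01 of the tile pixel count
and bilinear interpolation between tile mappings; a tile larger than the
image falls back to global equalization with a message.

## Resolution estimation

The edge-spread function is fitted as
$y(x) = A + B\,/\,(1 + e^{-k(x - x_0)})$ with offset and amplitude as
nuisance parameters (measured scans are not normalized), by least absolute
residuals: iteratively reweighted least squares around a
Levenberg–Marquardt core. Starting values are the median crossing for $x_0$
and $4/(x_{84\%} - x_{16\%})$ for $k$. Falling edges are detected and the
sign is carried by the amplitude so that $k > 0$ always. The line-spread
function is the numerical gradient of the fitted ESF on a fine grid
(step ≤ 0.1/k enforced) and its FWHM is read off by linear interpolation;
for the logistic this approaches $4\ln(1+\sqrt{2})/k$, the closed form the
tests pin (k = 0.47 µm⁻¹ ↦ 7.50 µm).

## Layer separation

The separation surface between the capillary plexus and the deep vessels is
found without any planarity assumption:

1. Frangi-type multiscale vesselness (β = 0.5, bright-ridge polarity) on the
   CLAHE MAP, at small scales {5, 10, 15} µm and large scales
   {25, 40, 60} µm matching the two diameter regimes.
2. Support points: pixels whose small-vessel response exceeds the 0.9
   quantile while the large-vessel response stays below the 0.7 quantile.
   Both quantiles are taken over *structure* pixels (response above 0.2 of
   the map maximum): image-wide quantiles would be dominated by the empty
   background and gate on noise. Each support pixel contributes its depth
   index, which sits on a capillary.
3. Two complementary surfaces through the support depths: a local
   moving-least-squares plane interpolation (accurate, noisy) and a global
   fifth-order bivariate polynomial least-squares fit on centered/scaled
   coordinates (smooth; degree lowered automatically if rank-deficient).
   Their average is used inside the convex hull of the support; outside it
   only the polynomial extrapolates, clamped to the observed capillary depth
   band — an unconstrained quintic extrapolates without bound.
4. The averaged surface is shifted 30 µm deeper (configurable): support
   depths lie *on* capillaries, roughly one clearance above the anatomical
   boundary. No published convention fixes this offset; 30 µm ≈ 3–4
   capillary radii reproduces the true boundary to well under the 40 µm
   surface-error budget on phantoms.

`split_volume()` then assigns each voxel strictly above the surface to the
superficial volume; the two halves sum to the original exactly.

## Vessel morphometrics

* **Binarization**: hysteresis — weak pixels at 0.135 (=$e^{-2}$) of the
  map's robust maximum, the 1/e² convention that keeps distance-transform
  diameters unbiased for Gaussian-profile vessels; strong seeds additionally
  require a vesselness-weighted amplitude above 0.3. Components without a
  seed, and objects under 5 px, are dropped.
* **Skeletonization**: Zhang–Suen thinning. Junctions are detected by the
  *crossing number* (number of distinct branches in the 8-neighborhood
  cycle), not the raw neighbor count — Zhang–Suen leaves staircase-redundant
  pixels on diagonal runs that a neighbor count misreads as junctions.
  Junction pixels are removed together with their 3×3 neighborhood (branch
  endpoints are diagonal neighbors of each other around a removed junction
  and would otherwise reconnect), branches are ordered by greedy walking
  with 4-connected preference, and segments shorter than 30 µm (≈ 4 lateral
  resolution elements) are pruned.
* **Diameter** = 2 × median Euclidean distance to background along the
  centerline (median is robust to junction bulges). Near the resolution
  limit diameters are overestimated — the known bias of any
  non-deconvolving method; the recovery tests bound the median relative
  error at 15% over 10–50 µm.
* **Tortuosity** = accumulated absolute turning angle divided by path
  length, in °/µm. The centerline is smoothed by a 3-point moving average
  and the turning stencil strides to chords of ≈ 30 µm: single-pixel chords
  alias the raster staircase into spurious turning of order 1°/µm, while
  for a circular arc the turning-per-length ratio is invariant to chord
  length, so genuine curvature is preserved (semicircle of r = 100 µm ↦
  0.573°/µm within 1%). Each turning vertex is weighted by the mean length
  of its two chords, which removes end-effect bias on short arcs. A straight
  centerline measures exactly zero.
* **Angular alignment** = $\cos 2\Delta\theta$ between the segment's
  (undirected) end-to-end orientation and the radial direction from the
  wound center through its midpoint: +1 radial, −1 circumferential, 0 under
  isotropy. The cos 2θ form is a declared convention (vessels have no
  intrinsic direction); recovery of any particular published alignment
  value is not claimed.

## Wound-level aggregation

The vascularized-area mask is derived from the vessel mask by morphological
closing with a 300 µm disk followed by filling of enclosed holes smaller
than the closing-disk area. 300 µm bridges the inter-capillary spacing of
densely vascularized skin while indenting a wound-scale circular bed by only
$r^2/2R$ (≈ 36 µm for a 1.25 mm wound) — an avascular bed smaller than the
closing disk is, by the same token, no longer detectable, which is the
physical resolution limit of any area-based re-vascularization measure.
Scores are measured inside the original wound outline (in practice marked on
day-of-wounding photographs; in simulations known exactly): re-vascularized
fraction = vascularized area within the outline / outline area. The wound
center is the centroid of the largest enclosed non-vascularized component;
components touching the image border are peripheral coverage gaps, not
wounds, and are excluded.

Healing kinetics are fitted as a plain two-parameter logistic by
Levenberg–Marquardt least squares; the rate curve is the normalized
numerical gradient of the fit and peaks at $t_0$ by symmetry. Fits require
at least four timepoints and refuse degenerate (non-progressing) score
series.

Heat maps pool vessels across wounds after re-expressing positions relative
to each wound's center (pooled vessels, not per-wound bin means), bin them
into 400 µm × 400 µm cells over a 6 mm extent, and report per-bin means
with counts; empty bins are `NA`, never zero. Radial profiles do the same
per annulus and per timepoint group. For trend analysis across a healing
series the reference point is the *original* wound center — a healed wound
has no measurable center, and the apparent center is only a fallback.

The superficial-vs-deep diameter comparison uses the classical equal-variance
two-sample Student's t-test on per-wound median diameters (Welch variant by
flag), with normal-theory 95% confidence intervals; no multiple-testing
correction is applied to this single comparison.

## Numerical and interface decisions

* Coordinates: x is the fast scan axis, y the slow axis, z depth increasing
  downward; physical positions are zero-based voxel centers, all in µm.
* All randomness flows from explicit integer seeds; identical configurations
  are bit-identical, and generators restore the caller's RNG state.
* Volumes and projections are stored as RDS with a human-readable JSON
  sidecar (no TIFF codec is available to the package without further
  dependencies); all tables are CSV.
* `run_pipeline()` validates its configuration before any computation,
  writes the effective configuration and package version next to the
  outputs, and produces byte-identical CSVs on re-run.

## Known limitations

* Morphometrics are measured in the 2D projection plane with per-point depth
  annotation; out-of-plane path length is not accumulated.
* Diameters near the lateral resolution limit are overestimated; no
  deconvolution correction is attempted.
* The measured tortuosity of strongly wiggling vessels is compressed toward
  lower values by the finite chord length (a low-pass in curvature);
  orderings across conditions are preserved, absolute high values are not.
* Axial resolution is taken as given by the detector bandwidth and is not
  estimated from data.
* Re-vascularization below the closing-disk scale (≈ 300 µm) is
  indistinguishable from full closure.

## Practical scale

A full-resolution single scene (7 × 7 mm² × 1.5 mm at 10 µm lateral / 5 µm
axial voxels) occupies ≈ 1.2 GB; the wound-series generator therefore
defaults to 10 µm axial sampling over 1 mm of depth — still three-fold
oversampled relative to the 35 µm axial resolution — and to the 20–30 µm
capillary population resolvable at that sampling, so that a four-timepoint
series plus its split volumes stays within a few GB. Full axial resolution
remains available per scene through `phantom_config()`.
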