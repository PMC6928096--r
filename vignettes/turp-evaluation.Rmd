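---
title: "Quantitative evaluation of simulated TURP: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative evaluation of simulated TURP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turpeval)
```

## The evaluation model

Transurethral resection of the prostate (TURP) removes hyperplastic
central-zone tissue around the urethra; the outer peripheral zone must
be preserved. `turpeval` scores a resection from co-registered pre- and
post-surgery image stacks sliced perpendicular to the urethra, using
three per-slice statistics averaged over the evaluable slices:

* **Preservation** `R_pres`: mean ratio of post- to pre-surgery
  *minimum peripheral-zone thickness*. Thickness is implemented as the
  minimum, over boundary pixels of the inner region (cavity plus
  central zone), of the Euclidean distance to the nearest background
  pixel — the shortest breach path. This semantics reaches 0 exactly at
  a perforation, which is the safety reading of "minimum thickness of
  the layer": a perforated slice contributes 0 to the mean rather than
  being dropped.
* **Smoothness** `R_smoo`: mean cavity solidity (area over convex
  area) of the post-surgery slices; 1 for convex cuts.
* **Circularity ratio** `R_circ`: mean post/pre ratio of
  `C = 4*pi*A/P^2`.

Aggregates are means over exactly the slice pairs valid in *both*
stacks; a pair is excluded (with a logged reason) when either slice is
flagged by segmentation, has a degenerate cavity (under 5 pixels), a
zero pre-surgery thickness, or a zero pre-surgery circularity.

## Discrete geometry conventions

Raster shape measurement is where naive choices silently bias the
scores, so the conventions are spelled out here and enforced by
brute-force oracle tests.

**Perimeter and circularity.** The cavity outline is the 0.5-level
marching-squares contour of the binary mask, simplified with
Douglas–Peucker (epsilon 0.9 px; anchors chosen by centroid distance so
the result is stable under grid rotations). The raw contour
over-measures boundaries by up to ~7 % through staircase artifacts,
which alone biases circularity down by ~12 %. Circularity is therefore
computed from the *simplified polygon's own* shoelace area and
perimeter. Pixel-count area combined with a sub-pixel perimeter is
off by a half-pixel boundary band, and no smoothing strength fixes the
disc and the square at the same time; the self-consistent polygon gives
`pi/4` exactly for axis-aligned and rotated squares and ~0.99 for
digital discs of radius 50 px. Reported `A_uret_mm2` remains the pixel
count times pixel area.

**Solidity.** The convex area is the *convex image*: the convex hull
of the mask's pixel centers, rasterized at pixel centers and unioned
with the mask (the convention of the common region-properties
implementations). Solidity is then exactly 1 for the rasterization of
any convex region and never exceeds 1. A corner-point hull with
shoelace area was considered and rejected: for a digital disc of radius
80 px it yields 0.986, i.e. a ~1.4 % penalty for a perfectly smooth
cut, which would swamp the 0.01 tolerance on the disc-cavity identity.
The price is that concavities narrower than ~2 px are under-measured;
resection cavities are blob-like, so this regime does not occur in
practice.

**Thickness.** Exact squared Euclidean distance transform
(Felzenszwalb–Huttenlocher two-pass, in C++), measured from background
pixel centers; 0 is returned as soon as the inner region is 8-adjacent
to background. Discretization error is below one pixel, matching the
all-pairs oracle exactly.

**Connectivity.** 8-connectivity for foreground regions, 4-connectivity
for the complement (hole filling) — the standard digital-topology
pairing that avoids connectivity paradoxes.

## The synthetic phantom: what it emulates

The generator states a world and keeps it fixed:

* **Geometry.** Peripheral and central zones are coaxial
  superellipsoids (the published phantom's CAD meshes are not
  available; superellipsoids reproduce the two-zone slice topology).
  Default bounding box 40 x 32 x 35 mm. The default shape exponent
  1.732 makes the default phantom 20.0 cm^3 — the average prostate
  volume that motivated that bounding box — where a plain ellipsoid
  would give 23.5 cm^3. Central zone scale 0.65 per axis leaves a
  5.6–7 mm peripheral wall at the equator; urethra radius 2 mm; 0.5 mm
  slice spacing; 0.2 mm pixels (ultrasound-realistic lateral
  resolution).
* **Slices.** A pixel belongs to a region when its center lies inside
  the continuous boundary. Slices are centered on the phantom equator
  and may extend into the embedding agar (the reference acquisition
  scanned the embedding box, which is taller than the phantom);
  tissue-free slices are valid images but invalid for metrics. The
  stated slice-count invariant (slices within the phantom height)
  contradicts the reference 153-slice acquisition and was relaxed to
  the embedded block height.
* **Resection.** Per slice, tissue inside a star-shaped boundary
  around the (offset) urethra axis becomes cavity:
  `r(theta) = R_mean * (1 + A * g(theta))` with `g` a random
  trigonometric polynomial on the configured harmonics (unit variance,
  Gaussian coefficients), clipped to the central-zone boundary. With
  per-slice probability `p` a breach extends the cut into the
  peripheral zone by a fraction `d` of the local wall thickness, as a
  raised-cosine bump (default 40 degrees wide) at a uniform random
  angle — smooth bumps avoid single-pixel artifacts. The random stream
  advances identically whether or not a slice breaches, so depth sweeps
  under one seed are slice-by-slice comparable (this underlies the
  monotonicity property test).
* **Appearance.** Label mean intensities ordered central (0.85,
  contrast agent) > peripheral (0.50) > embedding agar (0.15) > cavity
  (0.02, water); multiplicative unit-mean speckle derived from a
  Rayleigh variate with variance 0.02; 0.2 mm Gaussian blur as the
  point-spread stand-in. These defaults keep automated segmentation in
  its working regime (per-region Dice >= 0.95), which is what the
  physical phantom's contrast agent was engineered to achieve.
* **Skill presets.** `expert` (roughness 0.05, 0.3 mm eccentricity, no
  breaches), `fellow` (0.15, 1.2 mm, 5 % breach risk at 30 % depth) and
  `amateur` (0.35, 2.5 mm, 80 % breach risk at 60 % depth) are chosen
  so the simulated preservation ratios land near the reported physical
  outcomes (~1 for expert/fellow, ~0.5 for amateur) and circularity
  decreases with decreasing expertise.

What the generator does **not** emulate: acoustic physics (attenuation,
shadowing, reverberation, refraction), fully developed speckle
statistics, registration error between pre and post scans, and
deformation of tissue by the instrument. A green segmentation or
ranking test therefore establishes correctness of the pipeline on
plausible geometry and contrast, not robustness to clinical ultrasound
artifacts.

## Segmentation

Deterministic percentile contrast stretch (1–99 %), then two-threshold
Otsu (exhaustive 256-bin search) or fixed cut-points; the chosen
thresholds are returned for provenance. Dark pixels are
background/cavity candidates; the cavity is the dark component inside
the convex image of the tissue mask containing (or nearest to) the
cavity seed, hole-filled. Using the tissue hull as the interior —
rather than "enclosed by tissue" — keeps the cavity detectable when a
full-depth breach connects it to the surrounding water, at the cost of
assuming a convex organ outline (true for the phantom). Morphological
cleanup uses Euclidean-disc opening/closing (radius 0.3 mm) built on
the distance transform; components under 1 mm^2 are absorbed. A slice
with no cavity candidate is flagged, never an exception. Seeds
propagate along the stack via the previous slice's cavity centroid.

The reference pipeline's manual contrast enhancement is replaced by the
deterministic stretch; its detection algorithm is unpublished, so these
defaults are declared choices, not reconstructions.

## Mechanics

Flat-punch relation `E = 2 (1 - nu^2) q a / w`. The source formula
calls `a` "the loaded area", which is dimensionally inconsistent; `a`
is implemented as the punch *radius* (3 mm) with `q = F / (pi a^2)`
the mean contact pressure, the classical rigid flat-punch solution of
that form. Defaults: Poisson ratio 0.495 (near-incompressible
hydrogel), 0.5 Hz, 2 % pre-compression, 10 run-in cycles skipped, 20
steady-state cycles used, located by rising zero-crossings of the
detrended displacement.

Amplitudes default to the Fourier fundamental at the drive frequency
rather than half peak-to-peak: additive noise biases peak-to-peak
upward (at 20 dB SNR by ~15–20 %, far outside the 5 % recovery
target), while the single-frequency projection is unbiased and matches
the phase estimator; `mode = "ptp"` remains available for distorted
waveforms. The phase gate (default 5 degrees) attaches a warning, not
an error, since the modulus of a mildly viscoelastic sample is still
informative. Whether the reference measurements used amplitude or peak
values is unstated; both modes are provided.

## Scoring and statistics

Scores are `100 x` the mean aggregate per operator, clipped to
[0, 100] (clipping cannot trigger for subtractive resections; the
tests assert this). Group comparisons use the equal-variance two-sample
two-tailed Student t-test at alpha 0.01 by default — the reference
analysis names only "two-sample t tests" and Excel's default is the
equal-variance form — with Welch available and recorded. No
multiple-testing correction is applied across the three parameters,
matching the reference design; with three tests at alpha 0.01 the
family-wise error remains below 3 %, but this is a documented
limitation, not a recommendation.

## Determinism and I/O

One top-level case seed deterministically spawns per-stage seeds
(resection, pre-render, post-render); identical configuration yields
byte-identical label TIFFs. Bundles are multi-page TIFF (uncompressed,
little-endian; 8-bit labels, 32-bit float intensities) with a JSON
sidecar carrying spacings, seeds, the label alphabet and provenance. A
minimal TIFF codec is built in because no R TIFF package is available
in the supported environment; it reads back only what it writes.
Run configurations are JSON; YAML is unsupported for the same
offline-dependency reason.

## Known limitations

* Shape metrics assume one cavity per slice; multiple disconnected
  resection pockets are reduced to the seed-matched component.
* Circularity of very small regions (radius < ~5 px) is
  resolution-limited; such slices should be, and are, excluded as
  degenerate only below 5 px — between 5 and ~20 px values carry a few
  percent of discretization noise.
* The renderer's intensity clipping to [0, 1] biases regional means
  that sit within ~2 standard deviations of the bounds; distributional
  checks are meaningful only away from the clip limits.
* The skill presets operationalize three operator classes plausibly
  but are not fitted to any measured operator population.
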