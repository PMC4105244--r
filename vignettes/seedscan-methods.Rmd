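---
title: "Grain segmentation, morphometry and colour calibration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grain segmentation, morphometry and colour calibration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscan)
```

This vignette documents the models and algorithms behind `seedscan`, the
parameters that matter, the design choices that were genuinely open, and what
the synthetic validation does and does not demonstrate.

## The measurement problem

A flatbed scan of scattered cereal grain on a dark backing is close to an
ideal segmentation setting: uniform illumination, high grain/background
contrast, approximately elliptical objects. The obstacles are mundane —
sensor noise, the dark ventral crease that can split a grain in two,
scratches and debris on the glass, and grains that touch. The pipeline
addresses each with a dedicated, deterministic step; nothing is stochastic,
so identical inputs give bit-identical label maps and CSVs.

## Segmentation

**Grey derivation.** The segmentation grey image is the mean of the red and
green channels. For seed colours (yellow–red–brown) these two channels carry
the contrast; blue mostly carries noise and is ignored.

**Preprocessing.** The grey image is simplified with, in order: Gaussian
smoothing (`gaussian_sigma_px`, default 1 px); an attribute *closing* with
width criterion 0.3 × minimum grain width (fills the dark crease from the
bright side); an elongation *thinning* (removes bright scratch-like
structures with moment-ellipse axis ratio above `elongation_threshold`,
default 5); an attribute *opening* with width criterion 0.7 × minimum grain
width (thin debris); and an attribute *opening* with length criterion 0.7 ×
minimum grain length (thick debris). The 0.3/0.7 factors are fixed fractions
of the user-declared smallest grain; millimetres convert to pixels as
`round(mm × dpi / 25.4)` with a 1 px floor.

Attribute (connected-component) operators act on max-tree nodes — connected
components of the upper level sets — and either keep a node at its level or
merge it into its parent. They are contour preserving: every output level-set
component is a component of the corresponding input level set, so no edge is
displaced, which matters because the same image later provides sub-pixel-fair
boundaries for size measurement. The max tree is built with the union-find
algorithm on pixels sorted by grey level (8-connected foreground), in
compiled code; a brute-force threshold-decomposition filter serves as the
test oracle on small random images.

**Attribute definitions.** The size attributes are the minor and major axes
of each node's moment ellipse (second central moments, with a 1/12 per-pixel
variance term so one-pixel-wide structures get a finite ~1.1 px minor axis),
and elongation is their ratio. Bounding-box dimensions were considered and
rejected: they are not rotation invariant — a thin crease at 45° has a large
bounding box in both axes, so a bbox-width closing fails to fill it and the
grain can split lengthwise along its crease. Moment axes treat every
orientation identically at the same cost.

**Thresholding.** A single global threshold separates grain from background.
Plain grey-histogram methods are biased by boundary pixels, whose mixed
values populate the valley between the modes. The threshold is therefore
computed on the low-gradient stratum of the bivariate (grey, gradient)
histogram: pixels whose central-difference gradient magnitude is at most the
image median. Within that stratum the split maximises the between-class
variance of a ≤256-bin histogram. When the optimum is a plateau (an empty
grey gap between modes), the midpoint of the plateau is returned — any value
on the plateau induces the same partition, and the midpoint maximises the
margin to both modes. A guard precedes thresholding: if the preprocessed
image's dynamic range is under 10 grey levels, the scan is declared empty —
grain on a dark backing carries an order of magnitude more contrast, and
without the guard a variance-maximising split would happily "segment"
residual noise in a grainless scan.

**Splitting and filtering.** Touching grains are separated by watershed
flooding of the Gaussian-smoothed (`dt_sigma_px`, default 2 px) Euclidean
distance transform, restricted to the thresholded mask; seeds are the
regional maxima of the smoothed distance map. The smoothing merges the
spurious maxima a discrete distance map develops along an elongated grain's
ridge. Flooding occasionally leaves a mask pixel unassigned; such pixels are
attached to the nearest label so that the parts partition the mask exactly —
a conservation property the tests assert pixel for pixel. Finally, regions
smaller than 0.5 × minimum grain width × length (in pixels) are removed and
survivors are relabelled 1..n.

## Morphometry

Per grain: area is the exact pixel count times `(25.4/dpi)²` — no estimator
ambiguity, asserted to machine precision. The perimeter uses a
Cauchy–Crofton 4-direction estimate (transition counts along rows, columns
and both diagonals with spacings 1, 1, 1/√2, 1/√2, averaged with weight
π/2): unbiased for smooth convex shapes, within ~3% for digitised discs of
grain-like radius, with a known few-percent bias for axis-aligned polygons —
acceptable because grains are elliptical. Length and width surrogates are
the moment-ellipse axes (`majellipse`, `minellipse`), rotation invariant
within 2% in the tests. The orientation comes from the same moments and
feeds the crease detector.

Square pixels are assumed (scanners guarantee this); a single dpi serves
both axes. dpi precedence: an explicit argument beats file metadata; a
missing dpi with no configured value is an error, never a silent default.

## Colour

Scanner RGB is device dependent. Calibration scans a 24-swatch ColorChecker
card under the same settings and fits a single affine map
`Lab = M·RGB + o` jointly over the three CIELAB channels by least squares on
the swatch means against a reference table (shipped: the widely published
D50/2° values for the classic 24-patch card; any CSV with `swatch_id, L, a,
b` can substitute — reported L\*a\*b\* values are in the illuminant of the
reference used). The training residual is summarised as the RMS Euclidean ΔE
over the swatches. An affine model is deliberate: it is what a scanner's
linear sensor response justifies, it is exactly recoverable from noiseless
data (a machine-precision test), and it commutes with averaging — so
applying the map to a grain's mean RGB equals averaging per-pixel Lab, and
only means need be transformed.

Swatch extraction finds locally uniform (low-gradient) regions of the card
scan, keeps the 24 candidates of mutually consistent area that avoid the
image border, estimates the card's rotation from the principal axis of the
swatch centroids (validated to 5°), orders the swatches row-major in the
card frame, and averages the central 50% of each cell, border-safe.

The fitted matrix and offset are serialised as two float TIFFs with the
`*RGB2Labmat.tif` / `*RGB2Laboff.tif` suffixes. The general-purpose TIFF
writer available to R cannot emit float sample formats, so the package
includes a minimal single-strip 64-bit-float TIFF writer/reader for these
two artifacts, giving an exact save/load round trip; its layout is
cross-checked in the tests.

## Crease detection

Wheat grains have a dark longitudinal crease; when a grain lies crease-up,
the crease area can bias colour means. Detection per grain: (1) mean-filter
the grey image along the grain's major axis (window `crease_k`, default
9 px, clipped to the grain mask) — this suppresses texture while preserving
any axis-parallel dark valley; (2) resample the grain into an axis-aligned
frame by nearest neighbour (inverse mapping, so the frame is hole-free and
colour values are never interpolated); (3) find the minimum-cost
left-to-right path with lateral steps of at most one row per column —
dynamic programming, ties broken to the smaller row; (4) declare a crease
when the grain mean exceeds the path mean by more than `crease_tau` grey
levels (default 15; a user-visible knob, since no principled universal
value exists); (5) grow the crease mask from the path over the contiguous
dark valley (pixels below grain mean − τ/2).

Two implementation details proved necessary. The path is confined to the
grain interior (distance to boundary > 2 px): anti-aliased boundary pixels
are dark for the irrelevant reason of being half background, and otherwise
attract the path, producing false positives. And a path may begin at the
first admissible column of the frame, because a steeply oriented grain's
bounding frame can have empty corner columns.

Colour is then reported in three modes: GS (whole seed, always), GSncd
(grains with no crease detected) and GSwc (non-crease region of creased
grains). The whole-grain mean is by construction the area-weighted mean of
the crease and non-crease means; the tests assert this identity to 1e-12.

## Synthetic study conditions

The generators are first-class, tested code and define the conditions under
which the pipeline is validated.

`render_grain_field()` places elliptical grains on a jittered grid (touching
pairs share a cell, overlapping ~2 px side by side), rasterises each grain
at 4× supersampling for realistic anti-aliased edges, optionally carves an
axial dark crease stripe (central 85% of the axis), and adds Gaussian pixel
noise. Truth labels mark pixels with ≥ 0.5 ellipse coverage. The wheat
preset draws length 6.7 ± 0.35 mm and width 3.4 ± 0.18 mm at 300 dpi — mean
grain area ≈ 18 mm², matching typical bred wheat — on a level-16 background
with body colour (168, 128, 92) ± 8 and noise sd 2, i.e. ≈130 grey levels of
grain/background contrast. A Brachypodium-like preset (8.71 × 1.47 mm) tests
shape generality; its axis ratio of ~6 exceeds the default elongation
threshold of 5, so configurations for such species must raise
`elongation_threshold` (to ~10) — a species-dependent parameter, documented
rather than hidden.

`render_colour_card()` renders the swatch grid from the *exact* inverse
image of the reference Lab values under a fixed, invertible ground-truth
affine map (chosen once so all 24 patches are in gamut), on a dark card
body against a mid-grey bed, with optional rotation, blur and noise. Two
precision subtleties: exact-recovery tests use the generator's
pre-rasterisation swatch set, since any 8-bit render quantises the truth;
and the residual-versus-noise monotonicity is measured on 16-bit renders,
because at 8 bits the deterministic ~0.5-grey rounding bias of a noise-free
render exceeds the effect of sd-0.5 noise (which dithers it away).

**What passing does not show.** The generator emulates geometry, contrast,
touching and the crease; it does not model scanner shadows, dust, husk
fragments, seed-coat texture, specular highlights or non-elliptical grain
outlines. Real scans will need the size parameters set per species and may
show a few percent absolute perimeter differences versus other software,
since perimeter estimators differ. The headline validation quantities
(count recall/precision, size errors, crease rates, colour-mode agreement)
are therefore statements about the method's correctness under controlled
conditions, not field accuracy claims.

## Validation problem sizes

The acceptance suite uses twenty scenes of 50–654 grains (the upper end
matching a typical real scan) for count recovery; 60 grains against
analytic ellipse truth for size accuracy; a 200-grain suite at crease depth
40 grey levels for crease sensitivity/false positives; and eight 300-grain
scenes spanning a ±20% body-colour range for the GS/GSncd/GSwc agreement —
per-scene means over hundreds of grains are what make correlations above
0.99 a fair expectation, mirroring how real scans average over whole
packets. These sizes were chosen as the smallest that keep sampling noise
well below each criterion's margin.

## Known limitations

- Background must be darker than the grain; light backgrounds are out of scope.
- The elongation threshold couples species shape to scratch removal; very
  elongated seeds require raising it, which also retains longer scratches.
- Crease detection assumes a single dominant axial valley; forked or faint
  creases (< ~15 grey levels of contrast) fall below the default τ.
- The affine colour model cannot absorb nonlinear scanner response; strong
  nonlinearity shows up as a large training ΔE, which the QC report surfaces.
- Label TIFFs store at most 65535 objects (16-bit), ample for real scans.
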