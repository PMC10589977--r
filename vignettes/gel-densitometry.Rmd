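---
title: "Gel densitometry with geldens: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gel densitometry with geldens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geldens)
library(tibble)
```

## The measurement model

A gel electrophoresis image records, for each sample lane, how much labeled
material accumulated at each migration distance. `geldens` models the image
as a non-negative intensity raster in *signal-high* polarity (more signal =
larger value), with rows running in the migration direction. The quantity
of interest for a band is the integrated intensity above background over a
chosen vertical region of one lane.

The chain of operators is:

1. **Polarity and luminance at read time.** RGB inputs are reduced to
   Rec.709 luminance (0.2126 R + 0.7152 G + 0.0722 B); images with dark
   bands on light background are inverted (`max − pixels`) once at read
   time. Fixing one polarity convention at the boundary removes an entire
   class of sign errors downstream.

2. **Whole-image background.** The default estimator is the rolling ball:
   background = grayscale opening of the image with a flat disc of radius
   `radius`. The opening removes any feature the disc cannot fit inside —
   bands — while following smooth structure — illumination gradients,
   diffuse stain. The residual `image − opening` is the working image.

3. **Lane geometry.** A lane is a polyline of nodes *(y, x, w)*: center
   column *x* and half-width *w* at row *y*, interpolated linearly.
   Node rows must strictly increase. This is deliberate: the profile in
   the next step is defined as a function of the row coordinate, which is
   only single-valued if the lane never runs horizontally.

4. **Profile.** For each integer row, the lane intensity is the sum of
   pixels whose integer column center lies within the half-width of the
   interpolated lane center, clipped to the image. Integration is along
   the row, *not* perpendicular to the path. Perpendicular sampling would
   require interpolation and would break the exact pixel-sum semantics
   that the test oracles rely on; for realistic lane curvatures (a few
   degrees from vertical) the difference is far below other error sources.

5. **Baseline and bounded integration.** Each lane carries a
   piecewise-linear baseline through user anchors *(y, b)*, constant
   beyond the end anchors, default identically zero. The raw measurement
   over the half-open region `[y0, y1)` is the discrete sum of
   profile-minus-baseline. Units are intensity·px² and are reported as-is;
   only ratios of these values are meaningful across images.

6. **Normalization.** With raw value $v_i$ and loaded protein $m_i$, the
   per-image reference value over the $R$ reference lanes whose
   measurements are marked successful is
   $$r = \frac{1}{R} \sum_{i=1}^{R} \frac{v_i}{m_i},$$
   and every successful lane $j$ gets
   $$w_j = \frac{1}{r}\,\frac{v_j}{m_j}.$$
   Two identities follow algebraically and are enforced to numerical
   precision in the test suite: the mean of $w$ over an image's successful
   reference lanes is exactly 1, and $w$ is invariant to any global
   intensity rescaling of the image (because the flat-disc opening is
   exactly scale-equivariant, $v \mapsto kv$ and $r \mapsto kr$ cancel).

Normalization is strictly per-image. Comparability across gels comes from
physically loading the same reference sample on every gel, not from a
statistical cross-gel model; the package deliberately adds none.

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `radius` (rolling ball) | px | 50 | Must exceed the largest band half-height but stay below lane spacing scale; 50 px suits typical 300–1500 px blot scans. Larger values leave more diffuse background in place. |
| `percentile` (flat percentile) | fraction | 0.2 | Alternative global background: subtract a single intensity quantile; useful for very flat membranes. |
| lane `half_width` | px | — | Should cover the band at ≥ 3 horizontal sigmas; a band of spread $\sigma_x$ tolerates lane misplacement up to about $w - 3\sigma_x$ with <1% change in $v$. |
| baseline anchors | (row, intensity·px) | single anchor at 0 | `auto_baseline()` derives anchors from the mean profile in a window just outside the region (default: skip 1 row, average 5). |
| region `[y0, y1)` | rows | — | Half-open; choose ≈ ±4 vertical sigmas around a band to capture >99.99% of its mass. |
| `invert` | flag | FALSE | Set per image at ingest; recorded in the image record so replay uses the same polarity. |

## What the synthetic generator emulates — and what it does not

`synth_spec()`/`synth_gel()` render 2-D Gaussian bands whose centers follow
each lane's quadratic curve $x(y) = x_0 + c\,(y - H/2)^2$, on top of a
planar illumination gradient plus one broad Gaussian blob, with seeded
Gaussian pixel noise, clamped at zero. The defaults of
`default_synth_spec()` are the package's standard validation conditions:
360×300 px, 5 lanes with curvatures 1–4×10⁻⁴ px⁻¹ (up to ≈13 px lateral
drift, matching visibly curved Ponceau lanes), 3 bands per lane with
amounts 2–8×10⁴ and spreads σ_y ≈ 4–6 px, σ_x = 4 px, and noise at 1% of
the peak band intensity. Rendering evaluates densities at pixel centers,
so a band's pixel sum matches its injected amount to <0.5% — that injected
amount is the ground truth every end-to-end test measures against.

The generator does *not* emulate: saturation and blooming of
chemiluminescence, spatially correlated membrane texture, ladder bleed
into adjacent lanes, band smile/frown (tilted bands), or JPEG artifacts.
Passing tests therefore demonstrate correctness of the *computational
chain* given a faithful lane description, not robustness to every
pathology of real membranes — on real images the analyst still chooses
paths, baselines and regions, exactly as in GUI-based analysis.

## Numerical and design choices

* **Flat disc, not a true hemisphere.** The background opening uses a flat
  disc structuring element. A true "ball" (grayscale hemisphere) breaks
  scale equivariance: opening(k·image) ≠ k·opening(image) because the
  ball's height does not scale with the image. The flat disc keeps
  normalization exactly invariant to exposure changes, which is a property
  worth more than the slight shape difference of the background estimate.
* **Domain-restricted borders.** Erosion/dilation ignore out-of-image
  pixels (min over fewer samples) rather than padding with zeros. This is
  what makes the opening of a constant image the image itself, the opening
  idempotent, and the background residual exactly zero somewhere (at the
  global minimum). The implementation decomposes the disc into row runs
  and builds running minima incrementally (two `pmin` per half-width), so
  a 400×300 image with radius 50 opens in about a second; it is verified
  against a brute-force nested-loop oracle in the tests.
* **Binary pixel inclusion.** A column contributes to a profile row iff
  its integer center lies within the half-width — no fractional edge
  weighting. The sum is then exact, order-independent, and checkable
  against an independent loop; fractional weighting would buy sub-pixel
  smoothness at the cost of exact oracle equivalence, a poor trade for a
  reproducibility-first engine.
* **Discrete sums, not trapezoids.** Profiles are per-row aggregates of a
  discrete image, so the measurement is a plain sum. Additivity over
  abutting regions (`[a,b) + [b,c) = [a,c)`) is then *exact*, which the
  property tests assert with `identical()`.
* **0-based, half-open coordinates everywhere.** One convention for crops,
  paths, regions and serialized parameters; intervals compose without ±1
  bookkeeping.
* **Canonical JSON for the log.** Parameters are serialized with sorted
  keys and 17-significant-digit floats, so serialization is injective on
  doubles and replay equality is well defined down to the bit. Raw values
  are stored as SQLite REALs (IEEE doubles, exact); replay compares with
  `identical()`, not a tolerance.
* **Degenerate inputs.** A flat image subtracts to all zeros; a baseline
  above the signal yields a negative value with a warning (kept, since the
  success flag is the curation mechanism); an image whose reference lanes
  all failed raises a "no reference" error for normalization while raw
  export still works; a lane clipped by the left/right image edge is
  summed over the clipped columns and logged, since tight crops commonly
  cut the outer lanes.
* **Embedded store only.** The schema lives under a `gel_` prefix so that
  the same layout could sit in a named schema of a server database, but
  this package only opens single-file SQLite stores; "viewing mode" is a
  read-only connection, not an application state.
* **Spreadsheet export as CSV.** Export writes `raw.csv` and
  `normalized.csv` (RFC 4180, UTF-8) — a format every statistics tool
  ingests losslessly, and one whose round trip the tests can verify
  exactly.
* **Declarative analysis for the CLI.** The interactive steps of GUI
  analysis (lane drawing, baseline dragging) are replaced by a canonical
  JSON parameter file. This is a strictly stronger form of the
  record-everything principle: the input to the analysis is itself a
  reviewable document, and `replay` re-derives the outputs from it.

## Validation problem sizes

The shipped test-suite and acceptance computations use: 20 gels of the
standard 360×300 px conditions for end-to-end recovery (300 band
measurements; Pearson r and median relative error against injected
amounts); 100 random lane-table fixtures for the normalization identities
(tolerance 10⁻¹²) and 3 intensity scalings k ∈ {0.5, 3, 10} end-to-end
(10⁻⁹); 100 random raster/path pairs for the profile oracle (10⁻⁹);
stored-vs-replayed equality with `identical()` plus a tamper-detection
probe; 50 random images for the morphological properties; and 100 random
project hierarchies for the path round trip. These sizes give stable
statistics while keeping a full run in tens of seconds on one core.

## Known limitations

* No automatic lane or band detection: geometry is an input, by design.
* No molecular-weight calibration against a ladder lane.
* Horizontal (row-wise) integration slightly widens the effective lane for
  strongly tilted segments; with node spacing ≤ 20 rows and realistic
  curvature the effect is negligible, but near-45° lane segments would
  need denser nodes and a wider half-width.
* Replay requires the original image file at its recorded path with an
  unchanged content hash; the store records provenance, it does not
  archive pixels.
* The reference-lane model assumes the reference sample is loaded on every
  image to be compared; the package intentionally provides no batch-effect
  correction beyond it.
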