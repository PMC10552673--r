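---
title: "Quantifying dystrophic muscle histopathology: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dystrophic muscle histopathology: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclehisto)
```

## Scope and conventions

`musclehisto` quantifies four readouts of muscle disease from 2-D
cross-section images: membrane-damaged (Evans Blue Dye positive) fiber
counts, regenerating (embryonic myosin heavy chain positive) fiber counts
and sizes, CD68 macrophage percent-area, and Picrosirius-red collagen
percent-area. Every raster is processed as floating point on [0, 1]
(integer files are divided by the maximum of their bit depth on read),
indexed row-major with the origin at the top left. All sizes are in
pixels; no pixel pitch is assumed, so physical-unit conversion is the
user's responsibility. The blue (nuclear) channel is read and carried but
not used by any pipeline.

## Threshold selection

Two automatic global selectors cover the two imaging situations.

**Robust background** (fiber-scale identification). The sorted intensities
are trimmed by `trim_low` and `trim_high` (defaults 0.05 each;
`floor(fraction * n)` pixels per side), the retained pixels are treated as
approximately Gaussian background, and the threshold is their mean plus
`n_sd` population standard deviations (default 2 — lenient; larger is
stricter). The upper trim is also the foreground-removal step: no second
exclusion pass is applied. We use the population rather than sample
standard deviation; with 5% trims on thousands of pixels the difference is
far below any other source of variation, and the choice is fixed here for
reproducibility.

**Minimum cross entropy** (marker- and collagen-scale identification).
Candidate thresholds are the interior edges of a 256-bin histogram on
[0, 1] (the bin count is a package choice; it bounds threshold resolution
at ~0.004). For each candidate t, pixels split into background (x < t,
mean μ0) and foreground (x ≥ t, mean μ1), and we minimize Li's objective
η(t) = −Σ_bg x·log μ0 − Σ_fg x·log μ1, with zero-intensity pixels
contributing nothing and empty-class candidates skipped. The search is
exhaustive rather than iterative: 255 evaluations are cheap, and exactness
lets the test suite compare against a brute-force double-loop oracle
bin-edge for bin-edge. Ties break toward the smaller threshold; an image
with fewer than two distinct values returns its own value. Foreground is
closed on the bright side (ties at t are foreground).

Both selectors clamp the result to `[lower_bound, upper_bound]`. The
bounds are not a technicality: on an inverted fluorescence frame most
pixels are bright fiber interior, the trimmed mean + 2 sd exceeds every
pixel, and an unbounded robust-background threshold would classify the
whole frame as background. The shipped fiber-scale configuration therefore
caps the threshold at 0.8, which is what separates bright interiors from
the darker boundary network — the same bound adjustment a user of an
interactive pipeline performs when fiber detection fails on a frame.

## Segmentation

`identify_primary_objects()` runs threshold → fill holes → declump →
diameter filter → (optional) border discard → consecutive relabeling.
Objects must be brighter than their surroundings, so callers invert
laminin planes first. Holes are filled before declumping so the distance
transform reflects whole-fiber geometry. Components are 8-connected.

Declumping is shape-based: the Euclidean distance transform of the
foreground is smoothed with a Gaussian (`smoothing_sigma`, `"auto"` =
`min_diameter/4`), zeroed outside the foreground, and flooded by a
watershed whose maxima are detected within an `ext = min_seed_distance`
neighborhood (`"auto"` = `min_diameter/2`). Peaks rising less than half a
pixel of smoothed distance above their common saddle are merged. This
depth criterion is deliberate: convex fibers clipped by the frame edge
have long, flat medial ridges whose float-level wiggles would otherwise
seed spurious splits, while two genuinely overlapping fiber-scale objects
meet across a saddle several pixels deep and still separate. Increasing
`smoothing_sigma` monotonically suppresses splitting (the recommended fix
for over-segmentation; reduce it for under-segmentation). Watershed
assigns every foreground pixel to a basin — there are no unlabeled ridge
lines — so converting objects back to a binary mask conserves foreground
area exactly.

Size filtering keeps objects whose area-equivalent diameter
2·√(area/π) lies inclusively within `[min_diameter, max_diameter]`.
`discard_border` defaults to off: edge-clipped fibers are real fibers and
are counted. Both defaults are package conventions, stated here because
they change counts.

## The four pipelines

* **EBD.** Damaged fibers have degraded borders and resist direct
  segmentation, so the pipeline counts their complement. The image is
  inverted, the dye and laminin channels are averaged (normalized weighted
  mean, equal weights by default — a mean rather than a sum so the result
  stays on [0, 1]), and intensities are squared (`square_exponent = 2`,
  generalized to any positive exponent). Squaring darkens mid-gray,
  dye-filled fibers while bright intact interiors stay near 1, so the
  first identification pass counts only intact fibers. A second pass on
  the inverted laminin plane counts all fibers with the *same* fiber-scale
  parameters, so the subtraction compares like with like. A negative
  difference (the passes disagreeing) is clamped to zero and flagged with
  a warning rather than hidden.
* **eMyHC.** All fibers are counted from the inverted laminin plane;
  marker-positive fibers are identified directly on the un-inverted marker
  plane (they are already light on dark) and their pixel areas reported
  for the size distribution of regenerating fibers.
* **CD68.** Macrophages aggregate in necrotic regions and cannot be
  counted individually, so the readout is percent-area: minimum
  cross-entropy identification on the marker plane, objects to binary,
  area over the full frame.
* **Collagen.** The green plane of the brightfield image (where
  Picrosirius red gives the strongest collagen contrast) is inverted and
  segmented at myofiber-scale diameters; percent-area again uses the full
  image area as denominator — not the tissue area, a choice that matters
  if frames contain much non-tissue background.

Percentages are reported per image; aggregation across images or animals
is left to the user. Channel roles are explicit configuration because the
staining conventions differ between assays (damage assay: laminin green,
dye red; regeneration/inflammation assays: laminin red, marker green).

## Shipped default parameters

Defaults were fixed once against the synthetic scenes described below and
are all overridable per YAML config:

| parameter | fiber scale | marker scale | note |
|---|---|---|---|
| diameters (px) | 10–150 | 8–150 (eMyHC), 10–200 (CD68/collagen) | fibers here are ~30–80 px across |
| threshold | robust background, N = 2, trims 5%, cap 0.8 | minimum cross entropy | |
| threshold floor | 0 | 0.1 (eMyHC), 0.4 (CD68), 0.575 (collagen) | see below |
| declump | on, σ = 6, seed distance 12 | off | markers/aggregates need area, not splits |

The marker-scale floors implement a half-contrast rule: thresholding a
blurred object at the midpoint of its two intensity modes recovers the
sharp-edge area nearly unbiased, whereas the unbounded cross-entropy
threshold sits low and annexes the blur halo (for the thin interstitial
collagen ribbons this inflated a true 10% coverage to ~17% before
clamping). The floors equal the midpoints of the rendered modes (0.02/0.8
fluorescence markers → 0.4; a conservative 0.1 for eMyHC where per-fiber
intensity varies; 0.30/0.85 inverted brightfield → 0.575). A secondary
benefit: pure-noise frames never reach the floor, so healthy-control
images yield exactly zero foreground. On real data with different stain
contrast these floors are the first thing to revisit.

## The synthetic scenes

Ground-truth images stand in for the unpublished mouse microscopy. A scene
places `n_fibers` jittered lattice points (jitter: uniform, ±45% of the
lattice spacing by default), partitions the frame into nearest-point
regions — convex polygons that mimic the packing of real cross-sections —
and erodes each region by half the boundary width (default 3 px) to form
fiber interiors separated by a laminin network. Marker-positive fibers are
drawn by a ceiling rule (`ceil(fraction · n)`), optionally biased toward
the smallest third of fibers to reproduce the observation that
regenerating fibers are relatively small. Macrophage aggregates are
irregular unions of a main disk (radius ~15 px) and three rim satellites;
six of them cover ≈3.2% of a 400×400 frame. Collagen is grown outward
from the boundary network pixel-by-pixel in order of distance until the
target fraction is met, giving exact coverage. Rendering uses fixed
intensities (laminin 0.8 over 0.05; markers 0.7–0.9 over 0.02;
muscle/collagen brightfield triplets 0.85/0.70/0.55 and 0.75/0.15/0.20),
then per-channel Gaussian blur (default σ = 1, replicate-padded so frame
edges do not wrap) and additive Gaussian noise (default σ = 0.01), clipped
to [0, 1]. One private random stream per scene is derived from the seed;
no global state is touched.

Default frames are 400×400 px with 100 fibers (mean fiber diameter ≈45
px); validation uses 20-scene batches for counting and 3–6 scenes per
area assay, sizes at which the whole suite runs in a few minutes on one
CPU.

What the scenes deliberately do *not* model: tissue folds and tears, poor
or uneven laminin staining, background autofluorescence gradients,
fiber-type intensity mosaics, nuclei, and out-of-focus z-structure.
Passing the ground-truth tests therefore demonstrates the correctness of
the algorithms and their wiring, not robustness to every real-world
artifact — on real data the threshold bounds and declumping smoothing
still need per-dataset review, exactly as interactive pipelines require.

## Numerical and degenerate-input choices

* Thresholds are compared with ≥, so ties at the threshold are foreground.
* A constant image yields threshold = its value (σ = 0 limit) under both
  selectors, clamped to the bounds.
* An all-background frame after thresholding is a valid zero-object
  result, not an error; an all-foreground frame is a single full-frame
  object (the distance transform is unbounded there, so declumping is
  skipped) — at fiber-scale diameter bounds it is then removed by the size
  filter, which is why a blank image reports zero cells with a warning.
* Cross-entropy candidates with an empty class are skipped; if every
  candidate is skipped (all mass inside one bin interval) the midpoint of
  the value range is used.
* `ceil(marker_fraction · n)` is computed after rounding to 9 decimals so
  that e.g. 0.07 × 100 flags exactly 7 fibers despite binary floating
  point.
* CSVs are written in binary mode with plain decimal rendering, making
  repeated runs byte-identical.

## Known limitations

Structures thinner than the optics blur cannot have their area recovered
by any global threshold: under heavy blur (σ = 1.5) the ~2 px synthetic
collagen ribbons are unresolvable — measured coverage swings from ~4% to
~20% for a true 10% depending on threshold placement — while under the
default noise model (σ = 1 blur, 0.01 noise) recovery is accurate to
within ~0.2 percentage points. Counting assays are unaffected (fiber
counts stay exact or within ±1 at 3× the default noise). Whole-slide
formats, z-stacks and physical calibration are out of scope.
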