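---
title: "Quantifying complex scute color patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying complex scute color patterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scutepattern)
```

## The problem

Complex animal color patterns — blotches, interconnected stripes, blended
spots — resist the categorical descriptions ("spotted", "banded") that work
for simple patterns. The Eastern box turtle carries a bright yellow-orange
pattern on a dark shell whose scutes (the keratinous plates of the carapace)
make natural per-image analysis units: one scute is hand-outlined per view in
an exact digital green (RGB 0,255,0), a gray reference card of known physical
size provides both color calibration and the mm scale, and everything
downstream is automatic.

`scutepattern` implements that downstream pipeline: pattern extraction,
nineteen scalar pattern measurements, a replicate-based measurement-noise
framework, threshold sensitivity analysis, and majority-vote consensus
scoring of volunteer pattern categorizations. Because the interesting
empirical datasets are photographic and large, the package also ships a
synthetic scene generator with exact pixel-level ground truth, so every stage
is testable on a desktop with no data downloads.

## Calibration model

Photographs include an 18% reflectance gray card. Calibration is the standard
minimal linear model: each RGB channel is multiplied by
`target / mean(channel over card ROI)` and clipped to [0, 1], with
`target = 0.18` on the linear reflectance scale. The original workflow
delegated calibration to an external multispectral toolbox whose numeric
target is not published; the 0.18 linear target is this package's choice and
is exposed as `calibration_target` in `pipeline_config()`. Under uneven field
lighting, any uniformly lit sub-section of the card may be passed as the ROI.
The physical scale is `50 mm / (pixels along the card's 50 mm edge)`; at
typical camera distances this lands between 5 and 20 px/mm, so the 1 mm²
cleaning thresholds below span 25–400 px.

## The four-step extraction algorithm

Pixels within the scute are classified pattern/background:

1. **Dynamic threshold.** The yellowness proxy is the red-minus-blue
   difference `d = R − B` (yellow light is red plus green, with no blue). A
   pixel is pre-pattern when `d > tau * mean(d over the scute)`, with
   `tau = 1.10`. The threshold adapts to each scute's overall yellowness.
   If the scute-mean `d` is not positive (a bluer-than-red region), the rule
   is still applied literally and a warning is emitted — on such inputs the
   threshold is *below* the mean and the extraction is not meaningful, which
   the warning makes visible rather than hiding.
2. **Small-object removal.** Connected components (8-connectivity) smaller
   than 1 mm² — `round(mm² × (px/mm)²)` pixels — are removed as noise.
3. **Hole filling.** 4-connected background components fully enclosed by
   pattern and strictly smaller than 1 mm² are filled (glare and scattering
   punch single-pixel holes in solid pattern regions).
4. **Edge smoothing.** A morphological opening with a square structuring
   element of physical side 0.5 mm (at least 1 px) removes thin protrusions
   and one-pixel bridges between objects without changing object bulk.

The step order is literal; fragments that step 4 shrinks below the step 2
size are *not* re-filtered (there is no fifth step). Object connectivity is
8 and hole connectivity 4 — the customary complementary pairing. Erosion
treats everything outside the image frame as background, so the opening
keeps exactly the union of structuring-element placements that fit inside
both the pattern and the frame.

## The nineteen measurements

For a calibrated image, scute mask and binary pattern, `measure_all()`
returns: fractional area (FA), mean object eccentricity (E), peak length
(PL), perimeter/area ratio (PA), mean hue/saturation/brightness of the
pattern pixels (H, S, B), mirror symmetry (Sy), Euclidean color contrast
(ED), intensity contrast (IC), object count (Ob), mean object area (OA),
per-channel contrasts (RC, GC, BC), yellow contrast (YC, yellow = min(R, G)
per pixel), centrality ratio (CR), occupation factor (OF), and normalized
centroid offset (NO). Notes on the less obvious conventions:

* **Eccentricity** comes from the normalized second central moments of each
  object with the 1/12 unit-pixel-variance correction, so a single pixel is
  a circle (0) and a 1-px line tends to 1.
* **Perimeter** is the Moore boundary-tracing tour length with diagonal
  steps counted √2. **PA** is reported in physical units, mean perimeter
  (mm) over mean area (mm²); the k×k-square sanity value is 4/(k·mm).
* **PL** skeletonizes (Zhang–Suen thinning) the pattern within the scute and
  separately the background within the scute;
  `PL = 2·|scute| / (|skel_pattern| + |skel_background|) · mm/px` recovers
  the stripe period on striped patterns. The formula is symmetric in the two
  skeletons, so which one is called "valleys" and which "peaks" does not
  affect the value.
* **Hue** is averaged arithmetically, matching the original description; a
  pattern whose hues straddle the 0/1 wrap point would average incorrectly,
  but yellow-orange patterns sit safely near hue 0.1.
* **IC** converts to grayscale with the standard luma weights
  0.2989/0.5870/0.1140 (the original states only "converted to gray scale").
* Undefined values (empty pattern, empty background, degenerate
  denominators) are `NA` sentinels; downstream statistics drop them
  pairwise. `ED = sqrt(RC² + GC² + BC²)` holds by construction.

### The symmetry index

`Sy` is the maximum fractional pixel overlap between the pattern A and any
rigid placement of its mirror copy: mirror left-right, rotate the copy about
its centroid by each angle on a grid, round to pixels, then search integer
translations around the centroid-aligned position. Because the search covers
rotations and translations of the mirror copy, the initial mirror axis is
immaterial (a different axis corresponds to a rotation of the copy, which the
search visits; the test suite verifies this). The overlap is normalized by
|A| — the mirror copy has the same cardinality, so this equals
intersection-over-min; union normalization is available as an option.

Defaults: rotations ±180° in 5° steps with a 1° refinement pass around the
best coarse angle; translations at 1 px steps within ±25% of the larger
pattern bounding-box side; optional 2× block-reduction for patterns above
10⁴ px, which changes the index by at most about 0.02 (tested). Overlaps
for all translations of one rotation are computed at once by FFT
cross-correlation on a frame sized so that the circular indexing is
alias-free; counts are integers recovered exactly by rounding, so the search
equals exhaustive enumeration on the same grid (tested against a naive
enumerator on 100 random patterns).

## Measurement noise framework

Replicate photographs of the same view quantify acquisition noise. For two
replicates the coefficient of variation is the pairwise form
`|x1 − x2| / mean(x1, x2)` — with two points the sample standard deviation
underestimates spread; the pairwise form equals √2 times the two-point
standard CV exactly. Three or more replicates use `sd/mean` (sample sd,
n−1). Group CVs are averaged over individuals per (measure, view) and then
over the five views. An alternative normalization — replicate differences
divided by the view-level mean across all individuals — is available as
`normalization = "population"`; both variants appear in the original
description and neither is asserted as canonical. Across-individual CVs use
each turtle's replicate mean. The within/across ratio estimates how much of
the apparent between-individual variation is noise; CVs above 10% are
flagged as substantial (configurable).

Group comparisons (museum vs field) run three families per measure and view:
a t-test on means (Welch by default — the original does not state the
flavor; pooled is an option), an F-test on variances, and a CV-difference
test. The construction of the original "F-test on CVs" is unstated; the
default here is an F-test on values standardized by their group means, with
the Feltz–Miller asymptotic CV test as an alternative, and the choice is
recorded in the output attributes. Within each (test, view) family the 19
p-values are Benjamini–Hochberg adjusted.

Threshold sensitivity re-runs the extraction at ratios
{0.90, 1.05, 1.15, 1.30} against the 1.10 baseline and reports, per view,
the mean FA, its percent change from baseline, and the mean pairwise CV
between baseline and test FA. Lower thresholds always admit more pixels, so
percent changes are positive below baseline and negative above.

## Consensus scoring

Volunteers assign up to four of nine fixed categories per turtle. Per
category the consensus is `max(#0, #1)/n` ∈ [0.5, 1] (exact ties give 0.5);
the overall score is the arithmetic mean of the nine. Blank survey cells are
read as 0 ("category does not apply") with a logged count, and responses
ticking more than four categories warn but still score — the statistic is
well defined regardless. Correlation of each measurement (averaged over the
top-view replicates) with the consensus score uses Pearson's r with BH
adjustment across the 19 tests, plus a Cook's-distance screen (> 1 flags a
single influential individual) from the univariate regression.

## The synthetic scene generator

`generate_scene()` emulates the study photographs: a dark scute bounded by a
closed 2 px exact-green outline, yellow objects (discs, axis-aligned
stripes, disc-union blobs) strictly inside, and a uniform gray-card patch of
known pixel edge length elsewhere in the frame. Geometry is continuous and
rasterized by pixel-center inclusion, so ground truth (object count,
per-object pixel areas, fractional area over the interior) is an exact
tally. The outline ring is the set difference between the polygon fill and
its 5×5 erosion: every fill pixel adjacent to the complement lies in the
ring, so a 4-connected flood from the border can never leak inside, and the
flood-fill interior equals the erosion exactly.

Default study conditions: a 260 × 640 frame at 5 px/mm (within the 5–20
px/mm range of the calibrated photographs), a hexagonal scute about 40 mm
across, a true-size 50 × 30 mm card, disc radii 3–5 mm, additive Gaussian
sensor noise with sd 0.005 (about one 8-bit count), and a dark *brown*
background (RGB 0.12, 0.10, 0.08). The brown matters: real shell background
has R ≥ B, keeping the scute-mean red-minus-blue positive as the dynamic
threshold assumes. A bluish background flips the sign of the mean, and the
literal rule then classifies noise as pattern — the generator reproduces
that failure mode if asked, but the defaults represent the organism.
Replicate jitter emulates re-photographing: a scalar illumination gain
(sd 0.03), sub-pixel translation (sd 1 px) and small rotation (sd 1°)
applied to the scene geometry before re-rasterization, with the outline
redrawn exact afterwards (outlines are drawn digitally after calibration).

What the generator does **not** emulate: 3-D shell curvature and perspective
foreshortening (angle effects enter only as affine jitter), specular glare,
gradient illumination across the frame, and the soft, blended object
boundaries of real patterns. Passing tests therefore demonstrate
correctness of the algorithms on well-posed inputs, not robustness to every
photographic artifact.

## Numerical choices and known limitations

* mm²→px thresholds use `round()`, reproducing the 25 px (5 px/mm) and
  400 px (20 px/mm) endpoints exactly.
* Zhang–Suen thinning is anisotropic: rotating a pattern by 90° can change
  skeleton pixel counts by several percent on small patterns, so PL is only
  rotation-invariant to about 10% there (all pixel-count-based measures are
  exactly invariant; the boundary-tracing perimeter agrees within 1%).
* The symmetry search rounds rotated coordinates; rounding ties depend on
  coordinate parity, so Sy is reproducible exactly for a given pattern but
  can shift by a few overlap pixels (≲0.01) under a global 90° rotation.
* Eccentricity of a single-pixel object is 0 by the moment correction.
* Hue is a linear mean on a circular quantity (see above).
* The pairwise CV is undefined when the two replicates average to zero;
  contrast measures can legitimately be negative, and such groups are
  dropped with a sentinel rather than folded into means.
* Test problem sizes: 50 synthetic scenes for recovery checks, 100 patterns
  up to 30×30 for the symmetry-oracle equivalence, 1000-replicate null
  simulations for the t-test calibration, and a 500 px radial-gradient
  fixture whose super-threshold area is analytic in the threshold ratio —
  `FA(tau) = (1 − tau/3)²` for a linear radial gradient — against which the
  sensitivity table agrees within 1% relative.

## A worked run

```{r example, eval = FALSE}
dd <- tempfile("study")
simulate_dataset(dd, n_turtles = 2, n_replicates = 2, seed = 1)
res <- run_pipeline(file.path(dd, "manifest.csv"),
                    out_dir = file.path(dd, "results"),
                    survey = file.path(dd, "survey.csv"))
res$noise          # within/across CV ratio per measure
res$consensus      # per-turtle and per-category consensus
```
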