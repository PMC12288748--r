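# scutepattern

Quantifying complex animal color patterns from calibrated photographs,
developed around the yellow-on-dark shell pattern of the Eastern box turtle
(*Terrapene carolina*). Complex patterns — lightly connected blotches,
irregular stripes, blended spots — defeat categorical descriptions; this
package extracts the pattern of a single hand-outlined scute (shell plate)
from a gray-card-calibrated photograph and reduces it to nineteen scalar
measurements, together with the statistical machinery to tell genuine
between-individual variation from acquisition noise.

## What it computes

**Extraction.** Within the scute (delimited by an exact digital green
outline, RGB (0,255,0)), a pixel is pattern when its red-minus-blue value
exceeds a dynamic threshold, 110% of the scute mean R − B (yellow is red
plus green without blue). The raw mask is then cleaned at the physical scale
estimated from the 50 mm gray-card edge: connected components under 1 mm²
removed, enclosed holes under 1 mm² filled, and edges smoothed by a
0.5 mm-square morphological opening.

**Measurements.** Per scute: fractional area FA = Σ(pattern px)/Σ(scute px);
object count Ob, mean object area OA, mean eccentricity E and
perimeter/area ratio PA from connected components; mean hue/saturation/
brightness (H, S, B) of the pattern pixels; contrasts between pattern and
background in each channel (RC, GC, BC), in yellow = min(R, G) (YC), in
grayscale intensity (IC), and combined, ED = √(RC² + GC² + BC²); peak
length PL = 2·Σ(scute)/(Σ skeleton of pattern + Σ skeleton of background) ·
mm/px; centrality ratio CR, convex-hull occupation factor OF, normalized
centroid offset NO; and a mirror-symmetry index
Sy = max over discretized rigid transforms T of |A ∩ T(mirror A)| / |A|,
found by brute-force search over rotations and translations of the mirror
copy.

**Noise and inference.** Replicate photographs give a per-measure
coefficient of variation — the pairwise form |x₁ − x₂|/mean for duplicates
(√2 times the two-point standard CV), sd/mean for triplicates — compared
against across-individual CVs as a noise ratio, with a 10% substantial-
variation criterion. Group comparisons (museum vs field) run t-, F- and
CV-difference tests with Benjamini–Hochberg adjustment across the 19
measures. Threshold sensitivity re-extracts everything at ratios
{90, 105, 115, 130}% against the 110% baseline.

**Consensus scoring.** Citizen-science votes (nine fixed pattern categories,
up to four per turtle) are scored per category by majority proportion
max(#0, #1)/n ∈ [0.5, 1], averaged into an overall consensus per turtle, and
correlated (Pearson, BH-adjusted, Cook's-distance screened) with the
measurements.

A synthetic scene generator (`generate_scene()`, `generate_replicates()`,
`generate_survey()`, `simulate_dataset()`) produces study-like images with
exact pixel-level ground truth, so the full pipeline runs and is tested
without any photographic data.

## Worked example

```r
library(scutepattern)

sc  <- generate_scene(default_scene_spec(seed = 7))   # three yellow discs
msk <- extract_scute_mask(sc$image)
cal <- calibrate_gray_card(sc$image, sc$truth$card_rect,
                           mm_per_pixel = estimate_scale(sc$truth$card_edge_px),
                           turtle_id = "demo", view = "top")
pat <- extract_pattern(cal, msk)
measure_all(cal, msk, pat)
```

```
<scute_scene> 260 x 640 px, 3 object(s), true FA 0.1031, 0.2 mm/px
<binary_pattern> 3915 pattern px in 260 x 640 frame, 0.2 mm/px
<measure_set> turtle demo, top view, replicate 1
     FA       E      PL      PA       H       S       B      Sy      ED      IC
 0.1028  0.0000 20.1061  0.4926  0.1282  0.8126  0.4001  0.7875  0.4386  0.2669
     Ob      OA      RC      BC      GC      YC      CR      OF      NO
 3.0000 52.2000  0.3400  0.0350  0.2749  0.2749  0.7323  0.3001  0.0378
```

All three discs are recovered (`Ob = 3`); the extracted fractional area
0.1028 sits within 0.3% of the rasterized ground truth 0.1031; eccentricity
is 0 (discs are circles); hue 0.128 is yellow-orange; and the three discs
overlay their mirror image at 79% pixel overlap (`Sy`). The consensus worked
example — six volunteers voting '0' and four voting '1' on one category —
scores `category_consensus(c(0,0,0,0,0,0,1,1,1,1))` = 0.6, i.e. 60%
agreement.

For a full batch run, `simulate_dataset()` writes PNGs plus a manifest and
`run_pipeline()` turns them into `measures.csv`, CV tables, test tables and
consensus scores (see the vignette).

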