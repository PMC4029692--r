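---
title: "Fruit detectability under occlusion: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fruit detectability under occlusion: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitview)
```

## The problem

A harvesting robot working a greenhouse crop row must first *see* the fruits.
In a dense sweet-pepper canopy most fruits are partially or completely hidden
behind leaves from any single camera position, so the question is geometric:
how much does fruit detection improve as the camera is moved around the
plant — different horizontal angles, different elevations, small displacements
along the row — and how few positions suffice?

fruitview quantifies this with two statistics:

* **Fruit visibility (FV)** — for one fruit in one image, the percentage of
  the fruit's unoccluded image area that is actually visible, scored on a
  discrete level set `{0, 5, 10, 20, 30, ..., 100}` (note the scale has no
  15; `fv_levels()`).
* **Fruit detectability (FD)** — for one plant and a set of viewpoints, the
  percentage of the plant's *ground-truth* fruits whose FV meets a threshold
  in at least one image of the set. The threshold comparison is inclusive
  (`FV >= threshold`): a 40% threshold admits a fruit occluded by up to 60%.

Two conventions matter and are fixed throughout:

1. **The denominator is the fruit registry.** Every plant's fruits are
   censused independently of the images, so fruits invisible from *every*
   viewpoint still count against FD. A registered fruit with no record at a
   viewpoint is materialised with FV = 0, never treated as missing.
2. **Aggregation is mean-of-plants.** FD is computed per plant and averaged;
   the spread across plants is the sample standard deviation
   \(\mathrm{SD} = \sqrt{\sum_i (\mathrm{FD}_i - \overline{\mathrm{FD}})^2/(n-1)}\).
   An alternative — pooling fruits across plants before dividing — weights
   plants by their fruit counts; we reject it so that a heavily laden plant
   cannot dominate the session statistic, and keep the per-plant convention
   consistent between single viewpoints and combinations. The choice is
   isolated in one place (the weights inside the combination scan), so a
   pooled variant would be a three-line change.

## The viewpoint layout

`canonical_viewpoints()` returns the 14 labelled positions used by the
standard design: labels 10–14 sweep the azimuth (30°, 60°, 90°, 120°, 150°)
at zenith 90° (horizontal viewing, azimuth 90° = straight in front of the
row); labels 1–3, 4–6 and 7–9 fix azimuth at 90° and set the zenith to 120°
(looking down), 90° and 60° (looking up), each triple displaced by −0.15, 0
and +0.15 m along the row. Labels 5 and 12 have identical geometry but are
kept as distinct labels, so 14 labels give \(2^{14}-1 = 16{,}383\)
combinations. Which end of the row the negative offset points to is a
package convention; the source design only fixes the magnitude.

## Combination analysis

A fruit is detected by a *subset* of viewpoints if any member detects it, so
per-plant FD is monotone under subset union. `max_fd_by_size()` scans every
non-empty subset (internally as bitmasks over the label set, chunked so the
memory stays flat), records for each size \(k\) the maximum combined FD and
*every* subset attaining it — ties are deliberately retained, since many
subsets are typically optimal — and reports the smallest \(k\) whose maximum
equals the global maximum ("positions needed"). Exhaustive mode is capped at
20 viewpoints (\(2^{20}\) subsets); beyond that `greedy_cover()` adds the
viewpoint that newly detects the most registered fruits (ties broken toward
the lowest label), which is never better than the exhaustive maximum at any
size and is used as a sanity bound in tests rather than as the primary
result. FD equality for argmax ties and the positions-needed comparison uses
an absolute tolerance of 1e−9 on the percent scale, well below the smallest
possible FD difference for any realistic fruit count.

## The synthetic canopy simulator

No field recordings ship with the package; instead `generate_scene()` and
`simulate_session()` produce visibility tables with the geometric and
statistical structure of a greenhouse recording session, so every analysis
path can be exercised and property-tested end to end.

A scene is a crop row along the x axis (aisle at negative y, z up): plants
0.2 m apart, each with fruit spheres and zero-thickness opaque elliptical
leaf discs. The camera is placed by `camera_pose()` from (azimuth, zenith,
offset): viewing direction
\(v = (\sin\zeta\cos\alpha,\ \sin\zeta\sin\alpha,\ \cos\zeta)\), position =
target + offset − 0.5 m · v, matching a recording arc of 1 m diameter with
the sensor 0.5 m from the canopy. Per plant the target height is recentred
on the plant's lowest fruit, and fruits outside the 0.7 × 0.5 m capture
window around the target are dropped from the registry (they still occlude).

**Visibility by Monte-Carlo ray casting.** FV is defined on the projected
disc: `fruit_visibility()` samples points uniformly on the fruit sphere's
camera-facing disc and casts camera-to-point rays; a ray is blocked if it
intersects any leaf disc or any *other* fruit sphere strictly between camera
and point. We read "percentage of total fruit area seen without occlusion"
as projected image area — the quantity an annotator judges in a photograph —
and reject the alternative 3-D surface-area reading, which would count the
invisible back hemisphere. Continuous percentages are quantized to the FV
level set by `quantize_fv()` (nearest level, exact midpoints rounding down —
an observer protocol gives no rule, so we fix one deterministically).

**Calibration (invented, not measured).** Defaults in `scene_params()`:
2–4 fruits per plant of radius 0.04 m (10-plant sessions then carry roughly
30 fruits, matching the 29–35 per session of the emulated design), ~12
leaves per plant (Poisson) with 0.09 × 0.055 m semi-axes, fruit centres in a
1.00–1.35 m band with leaves slightly above (1.05–1.50 m), since fruits hang
below the foliage that shades them.

**The zenith effect.** Looking downward (zenith 120°) detects markedly fewer
fruits than looking upward (zenith 60°) in real canopies, because leaves
orient toward the light and are then roughly perpendicular to a downward
camera. The simulator reproduces the mechanism with `leaf_up_bias`
\(\in [0,1)\): leaf normals are pulled toward the phototropic direction
\((0,-1,2)/\sqrt 5\) — up and slightly toward the open aisle. For a
downward viewing direction \((0, 0.87, -0.5)\) such a leaf is nearly face-on
(\(|v\cdot n| \approx 0.83\)); for the upward direction it is nearly edge-on
(\(|v\cdot n| \approx 0.06\)). A purely vertical bias would *not* work: the
incidence factor is then symmetric between zenith 60° and 120°. At the
default bias of 0.6 the effect is present but moderate; property tests use
0.9 ("strong bias") where the direction of the effect is stable across
seeds.

**Randomness.** One root seed drives everything; scene generation and each
(fruit, viewpoint) ray stream use seeds derived by a small multiplicative
hash, so changing `n_rays` never changes the scene, and a session is
reproducible bit-for-bit from `(params, seed)`.

## What the simulator does and does not emulate

It emulates: the recording geometry, the registry-backed FD bookkeeping,
discrete FV scoring, occlusion by leaves and by neighbouring fruits, the
leaf-orientation zenith asymmetry, and session-to-session variation via leaf
density and seed. It does **not** emulate: human scoring noise, stems and
branches (configurable extra occluders are possible but off by default),
leaf curvature, lighting, colour, or within-season plant growth (a "later
session" is just another seed and density). Passing tests therefore validate
the *analysis machinery* and the *direction* of geometric effects, not the
numeric FD levels of any particular real crop.

## Numerical and degenerate-input choices

* Ray–occluder intersections require the hit strictly between camera and
  sample point (parameter in (1e−9, 1−1e−9)); grazing contacts at the sample
  point itself do not block.
* A conservative prune skips occluders farther from the camera–fruit segment
  than their bounding radius plus the fruit radius (every sample ray stays
  within the fruit radius of that segment), which keeps full 14-viewpoint
  sessions subsecond without changing any result.
* Cameras inside the target fruit or inside another fruit are errors, as are
  zenith angles of exactly 0° or 180° and plants with zero registered fruits
  (FD is undefined, never silently 0).
* SD with one plant is reported as `NA`, not 0.

## Problem sizes used in tests and scripts

The shipped analysis scripts simulate 10-plant sessions at 300 rays per
fruit–viewpoint pair; the test suite uses 2–4 plant scenes at 120–200 rays
for integration properties, 10,000 rays for the analytic half-occluder
check (Monte-Carlo error ≤ 2 percentage points), 50 random tables with up to
8 viewpoints for brute-force oracle equivalence, and 200 random tables for
the monotonicity properties. These sizes make the whole suite run in well
under a minute while leaving every statistic's sampling error far smaller
than the effects asserted.

## Limitations

Exhaustive enumeration is exponential; beyond ~20 viewpoints only the greedy
heuristic is offered, without an approximation guarantee beyond the standard
set-cover behaviour. The mean-of-plants convention makes session maxima
sensitive to plants with very few fruits (one fruit flips a plant's FD by
100 points), which is also why the sample SD across plants is large — a
faithful property of the emulated design, not an artefact.
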