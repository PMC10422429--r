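---
title: "Quantifying omnidirectional bee traffic: methods and design notes"
author: "beetraffic authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying omnidirectional bee traffic: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetraffic)
```

## The measurement problem

Forager traffic at the hive entrance is a practical proxy for colony health,
but on unmodified Langstroth hives bees enter and leave in every direction:
fast straight flights, slower zigzags, crawling landings and lateral passes.
`beetraffic` quantifies *omnidirectional* traffic: the count of flying-bee
detections across a video's frames, with no attempt to track trajectories or
separate individuals. The deliberate consequence is overestimation relative
to a per-individual count — a bee visible and moving through k frames
contributes k. The number is a traffic volume, comparable across videos of
equal length and frame rate.

The pipeline separates *what looks like a bee* (an object detector) from
*what actually moved* (frame differencing), and only counts detections that
both fire. That makes the method robust to a detector's static false
positives (hive texture, shadows) and agnostic to how the boxes were
produced: any `function(frameIndex, frame)` returning scored boxes plugs in.

## The motion-detection operator chain

`detectMotionRegions()` runs, in order: grayscale (luma weights
0.299/0.587/0.114); Gaussian blur with a 5×5 kernel; pixelwise absolute
difference; grayscale dilation with a 5×5 rectangular element, one
iteration; binary threshold with foreground strictly above 20; external
boundary tracing of 8-connected foreground components with collinear runs
collapsed to segment endpoints; and an area filter that discards contours
whose shoelace polygon area is below 1000 px. Each survivor's minimal
enclosing rectangle is a motion region attributed to the later frame; frame
1 of a video therefore has no regions.

Parameter notes, all exposed in `MotionParams()`:

* **Blur sigma.** Only the kernel size is prescribed, so sigma defaults to
  the kernel-only convention `0.3·((k−1)/2 − 1) + 0.8` (1.1 for k = 5) and
  can be overridden.
* **Dilation iterations.** One — the minimal reading of "is dilated".
* **Threshold semantics.** Foreground is value > 20; the boundary value 20
  is background. Conversely the detector score filter keeps scores ≥ 0.7 and
  alignment accepts distance ≤ 50 px: both boundaries inclusive, matching
  the stated "at least" / "≤" wording.
* **Area filter.** Uses the traced contour's polygon area, not the
  rectangle's. For a filled w×h rectangle the traced polygon has area
  (w−1)(h−1); tests pin the 999-vs-1000 boundary exactly.
* **Area-threshold scaling.** 1000 px is calibrated for 1080-row frames and
  does not obviously transfer to other resolutions; it stays an explicit
  parameter, and `scaledMotionParams()` rescales it proportionally to frame
  area (37 px for the 240×320 test geometry).
* **Borders and connectivity.** Convolution and dilation use replicate
  (clamped-index) padding; components are 8-connected. These conventions are
  not prescribed anywhere, so they are fixed, documented, and enforced by a
  brute-force per-pixel oracle test that reimplements the whole chain
  naively and must agree bit-for-bit on random frames up to 64×64.

Box centers are geometric: cy = y1 + (y2−y1)/2. A printed source formula
placing the center at y2 + (y2−y1)/2 — outside the box — is treated as a
typo for the geometric center.

## Alignment and the traffic count

Region centers are indexed in a kd-tree (authored in-package; radius queries
are checked against brute-force scans). A detection is motion-aligned when
at least one region center lies within `maxDistancePx` (default 50 px,
inclusive) of its box center; the recorded match is the nearest region, ties
broken to the lowest region index so runs are reproducible. Only existence
matters for the count, so the tie-break never changes a traffic number.
Alignment uses proximity (criterion C1) alone; the overlap criterion C2
belongs to evaluation, below.

## Seven-category evaluation

Each ground-truth-vs-pipeline event receives one of seven categories — four
true-positive kinds (flying motion confirmed, crawling/residual motion
confirmed, stationary with motion correctly absent, moving but motion
missed), two false-negative kinds (motion caught but detector missed;
both missed), and false positives. A motion region *supports* a box when it
satisfies C1 (center within the alignment radius) and C2, operationalized as
strictly positive rectangle intersection — the minimal objective reading of
a "visually detectable" overlap that was originally judged by a human.

Design choices where the protocol was manual and a program needs a rule:

* **Matching.** Detections are matched to truth greedily by descending box
  IoU, accepting positive overlap, with deterministic (gt, detection)
  tie-breaks. On planted unambiguous instances tests verify greedy equals
  the exhaustive optimal assignment.
* **Crawling vs stationary.** Taken from the ground-truth `state` field
  (the simulator derives it from displacement; for real videos it would come
  from a human audit file), not re-derived from pixels.
* **Gaps in the decision table.** A detected stationary bee *with* motion
  support is classed as the crawling-motion true positive (that category's
  description covers residual wing/orientation movement); an *undetected*
  non-flying bee has no category — only flying bees were annotated in the
  source protocol — and is left untallied.
* **Ignore regions.** Truth rows with state `IGNORE` mark areas where
  unlabeled bees may appear (e.g. partial occlusion at frame edges);
  unmatched detections intersecting them are excluded from all tallies.

The four metrics are implemented *as printed*, including the nonstandard
denominators (precision = TP/(TP+FN), recall = TP/(TP+FP)); accessors and
docs say so explicitly so nobody mistakes them for the standard definitions.
Totals across strata are computed by pooling counts, which reproduces every
published total metric cell; the arithmetic mean of stratum metrics (what
the published table's caption claims) does not — e.g. pooled precision
1210/4368 = 0.28 versus mean(0.39, 0.24) = 0.315 — so pooling is primary
and `metricMeans()` is kept as a secondary summary. Table reproduction
rounds half away from zero to 2 decimals.

## Energy accounting

`energyEfficacy()` implements EFF(M, A) = λ·M/A with λ = 100 ("10²"; every
worked example confirms that reading). Efficacy tables round the metric to
2 decimals before applying the formula, because that is the only order that
reproduces the published cells (0.17 → 0.43, not 0.1687 → 0.42). The
operational footprint rounds the per-logger monthly amount (672 h × 0.003
kW-h/h = 2.016 → 2.02) before multiplying by the logger count, again to
match the published arithmetic (141.12 + 10 × 2.02 = 161.32); the unrounded
value is also returned.

Documented errata in the source figures, computed from components here and
*not* reproduced: a total CPA of 351.55 kW-h whose components sum to 321.55;
a seasonal footprint printed as both 807.60 and 813.60 where 5 × 161.32 =
806.60; a logger rate written once as 0.003 and once as 0.0003 kW-h/h (only
0.003 yields the printed 2.02); and one efficacy cell (recall efficacy of
the largest model, printed 0.56) that no rounding of 100 × 1.00/170.74 =
0.59 can produce. The acceptance test for the efficacy table keeps the
published 0.56 as the expectation and fails on that one cell by design,
recording the discrepancy rather than papering over it.

## The synthetic scene generator

`simulateBeeScene()` renders bees as anti-aliased dark ellipses over a
static procedural background (smooth textured field, light landing-pad band
across the bottom fifth) and adds Gaussian pixel noise. Five trajectory
patterns reflect the qualitative flight classes seen at hive entrances:

* `STRAIGHT` — constant velocity with small heading noise; the fastest
  pattern (default 8–12 px/frame at 240×320).
* `INWARD_ZIGZAG` / `OUTWARD_ZIGZAG` — piecewise legs whose approach
  (vertical) component reverses sign 2–4 times, with net drift toward/away
  from the pad guaranteed by making with-pattern legs roughly twice as long.
* `LAND_AND_CRAWL` — flight to a pad point, then crawling (≤ 2 px/frame) or
  stillness; exactly one flying→landed transition.
* `PARALLEL` — lateral crossing with approach component ≈ 0.

Speeds are stated as defaults, not as measured bee kinematics — no
quantitative speed data exist for the patterns, only their ordering (straight
is fastest). Motion states are derived from rendered displacement with
config-exposed thresholds: FLYING ≥ 3 px/frame, STATIONARY < 1, CRAWLING
between. Ground truth emits tight ellipse bounding boxes for fully visible
bees only, mirroring an annotation protocol that labels only full-size
unoccluded bees. A fixed seed makes frames and truth bit-identical.

What the simulator does *not* emulate — and hence what passing tests do not
show about field data: wing-blur texture, illumination changes, wind-driven
background motion, lens fogging, occlusion by other bees, and detector
failure modes correlated with appearance. The oracle detector's errors are
statistically controlled (Bernoulli misses, Poisson spurious boxes, Gaussian
corner jitter) but unstructured; real detector errors cluster. The
end-to-end tests therefore validate the *pipeline logic* — counting,
alignment geometry, category bookkeeping, metric arithmetic — not detector
accuracy on real imagery, which is an input to this package, not an output.

## Problem sizes and determinism

The test suite runs scenes at 240×320 over 10–30 frames with 1–6 bees
(about a minute in total), brute-force oracle comparisons on 100 random
frame pairs up to 64×64, and kd-tree checks on scenes up to 1000 regions.
All randomness flows through explicit seeds: simulation draws happen inside
a seed-scoped RNG that restores global state, and the oracle detector seeds
each frame's stream as `seed + frameIndex` so results are independent of
call order. Degenerate inputs are defined, not accidental: empty detection
sets and empty region sets flow through every stage; a single-pixel
component traces to a zero-area contour and is filtered; metrics with zero
denominators return NaN with a warning.

## Known limitations

* No trajectory tracking, by design: the count is a volume measure and
  overestimates individuals in proportion to per-bee visibility time.
* MP4 containers are not decoded; frames must be pre-extracted to PNG
  (processing on the decoded sequence also keeps results
  container-independent).
* The 1000 px area filter and 50 px radius are resolution-bound defaults;
  users at other geometries must rescale (`scaledMotionParams()`) or
  re-calibrate.
* Crawling bees moving ≥ 1 px/frame still produce motion regions at
  simulation scale, so land-and-crawl scenes contribute some aligned
  detections after landing; that matches the taxonomy's crawling-motion
  true-positive category rather than contradicting it.
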