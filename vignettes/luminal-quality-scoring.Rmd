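---
title: "Scoring luminal visualization quality in colonoscopy video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring luminal visualization quality in colonoscopy video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumiqc)
```

## The problem

During colonoscopy the clarity with which the lumen and mucosa are seen
varies continuously: focus drifts, the lens approaches the wall, fluid and
motion intervene. Clinicians can grade visualization quality on a
four-point Likert scale — poor, almost poor, almost good, good — but such
ratings are subjective and two experienced raters frequently differ by a
band. `lumiqc` implements an objective surrogate: a per-frame sharpness
score, calibrated onto the same four bands, aggregated to clip level, and
validated against paired human ratings with ordinal statistics.

## The SFIL focus measure

The premise is that poorly visualized frames contain few crisp, in-focus
edges while well visualized frames contain many. SFIL quantifies this with
a steerable filter bank built from first-order Gaussian derivatives. For a
Gaussian of scale $\sigma$, the derivative kernel steered to orientation
$\theta$ is $\cos\theta\,G_x + \sin\theta\,G_y$; by steerability these two
basis responses span every orientation, so the bank costs two separable
convolutions regardless of the number of orientations. Per pixel we take
the maximum absolute response over $K$ evenly spaced orientations on
$[0, \pi)$, and the frame score is the mean of that feature over the frame
interior.

Choices a user can tune, with defaults and rationale:

* `sigma` (px, default 1.0) — the derivative scale. Small scale keeps the
  measure sensitive to the fine vascular edge detail that distinguishes
  "good" from "almost good"; larger values trade sensitivity for noise
  robustness.
* `n_orientations` (default 4, i.e. 0°, 45°, 90°, 135°) — four
  orientations suffice for the per-pixel max to be nearly rotation
  invariant (the test suite asserts 90°-rotation agreement within 1% when
  `n_orientations` is a multiple of 4).
* Border margin — aggregation excludes a `ceiling(3 * sigma)` px frame so
  reflection padding cannot bias the mean; frames must exceed twice the
  margin (and be at least 16 px) to be scorable.

The score is linear in image intensity: multiplying all pixels by $c > 0$
multiplies the score by $c$. We deliberately do not normalize per-frame by
contrast — the calibration stage absorbs overall scale, and normalization
would entangle sharpness with exposure. RGB input is reduced to luminance
with Rec. 601 weights before scoring. Two classical reference measures
(Tenengrad, variance of Laplacian) are provided under the same border
convention for comparison studies.

The literature contains both first- and second-order steerable focus
measures and several aggregation rules; the published description of SFIL
names the family but not the formula. The operationalization above —
first-order derivatives, per-pixel max over the bank, mean aggregation —
is this package's documented choice, fixed here because every downstream
number depends on it. The test suite pins it against a brute-force
direct-convolution oracle (explicitly sampled steered kernels, nested-loop
convolution) to 1e-10 on frames up to 32×32.

## Calibration to the four-point scale

`fit_thresholds()` maps scores to bands with three ordered cut-points
chosen to maximize training accuracy on labeled reference images.
Candidate cuts are the midpoints between adjacent distinct sorted scores
(any optimal triple can be shifted to midpoints without losing accuracy);
the search is exact via an O(m) prefix/suffix decomposition and is verified
against a literal O(m³) exhaustive search in the tests. Accuracy ties are
broken by maximizing the minimum inter-threshold margin, then by the lowest
thresholds — arbitrary but fixed and tested. Scores exactly on a threshold
classify into the *higher* band (lower-closed, upper-open intervals);
`classify_score(model, t2)` returns band 3.

Degenerate inputs are refused loudly: a missing band names the absent
bands, all-identical scores raise a degenerate-data error, and a model
stores the measure name and parameters it was fitted for, refusing scores
from any other measure. Because the fit depends on scores only through
their order, training accuracy is invariant under strictly increasing
transforms of the score axis (asserted on small instances).

## Clip-level estimation

`score_clip()` scores every frame (a `--stride` option subsamples when
speed matters) and flags out-of-body frames — recordings made before
insertion or after withdrawal — by a brightness/uniformity heuristic:
mean luminance above 0.7 and luminance SD below 0.12. Flagged frames keep
their scores but are excluded from estimation. The thresholds cleanly
separate the two generated frame classes; on real video they are a
configurable starting point, not a validated detector.

`estimate_clip_band()` reduces the valid frames' band multiset to one of
three outcomes: a single band, a contiguous range, or no estimate. The
rule: find the shortest contiguous interval of at most three bands whose
frame fraction reaches `min_support` (default 0.8); ties prefer higher
coverage of the interval's (lower) median band, then the lower band. A
clip with fewer than `min_valid_frames` valid frames (default 25, about
one second at 25 fps) — or one whose bands only concentrate on the full
1–4 span — yields no estimate. Capping intervals at three bands follows
the outcome taxonomy the method is meant to report (single, two-step and
three-step ranges, or nothing): an interval spanning all four bands
carries no information. The published pipeline did not state its
reduction rule; this one is a documented surrogate whose properties
(order invariance, monotonicity of interval width in `min_support`,
consistency at full support) are asserted in the tests.

## Agreement statistics

* **Goodman–Kruskal gamma**: $G = (C - D)/(C + D)$ over concordant and
  discordant observation pairs; ties are ignored, which suits heavily tied
  4×4 ordinal tables. Significance uses
  $z = G\sqrt{(C + D) / (n(1 - G^2))}$, the approximation implemented by
  mainstream statistical software; at $|G| = 1$ the variance collapses and
  the result is flagged as a boundary case with `p = NA` rather than 0.
  The implementation is checked against brute-force pair enumeration on
  random tables, plus the symmetry identities (transpose invariance, row
  reversal negation, count-scaling invariance).
* **Wilcoxon signed-rank** on paired ratings: zero differences dropped
  (classic convention, matching common software defaults; Pratt's variant
  is out of scope), midranks for ties. For 25 or fewer nonzero differences
  the two-sided p-value comes from the exact sign-flip distribution,
  computed by dynamic programming over doubled midranks and identical to
  full $2^n$ enumeration; above that, the tie-corrected normal
  approximation without continuity correction (cross-checked against
  `stats::wilcox.test`). All-zero differences are reported as perfect
  agreement with no test rather than an error.
* **Band-difference tables** count $|c_1 - c_2| \in \{0,1,2,3\}$ with
  percentages rounded half-up to one decimal, the convention of printed
  agreement tables.
* **Match percentages**: a single-band estimate matches a rating by
  equality; a range estimate matches when the rating lies inside it
  (containment — the natural reading of a range "matching" a rating, and
  the package's fixed convention). For rank-correlating estimates with a
  rater, a range contributes its lower-central band
  $\lfloor (lo + hi)/2 \rfloor$ and no-estimate clips are excluded.

## The synthetic generator

Phantoms emulate the features that drive a focus measure in endoscopy:
a dark central lumen with radial falloff, mild low-frequency mucosal
shading, 1–3 px curvilinear vessel strokes (random quadratic Bézier
curves — crisp oriented edges, the structure SFIL responds to), and
saturated specular discs. Ground-truth band is imposed by Gaussian blur:
σ = 6, 3, 1.5, 0.5 px for bands 1–4. This ladder gives cleanly separated
SFIL distributions at the default 256×256 frame size, mirroring a curated
reference set that experienced raters could classify consistently; at
small frame sizes (≤128 px) stroke-count variance makes adjacent bands
overlap, which the test suite exploits deliberately when it needs
imperfect calibration. Out-of-body frames are a bright near-uniform field
with mild noise. Rating pairs draw the absolute band difference from
user-supplied weights (defaults: 0.624, 0.325, 0.029, 0.022, the empirical
inter-clinician distribution), with uniform placement and a fair-coin
sign, so the requested discrepancy structure is recovered exactly in
expectation.

Every generator is a pure function of its spec and seed: frames are
bit-identical across calls and the caller's RNG stream is untouched. What
the phantoms do **not** model: stool, bubbles and fluid, motion blur,
illumination flicker, lens distortion, and real mucosal texture statistics.
Passing tests therefore demonstrate the pipeline's internal correctness
and its behavior under controlled defocus — not clinical performance.
The blur-ladder surrogate for the intermediate bands ("almost poor",
"almost good") is an assumption; no published definition of those
categories beyond clinician judgment exists.

## Problem sizes and numerics

The test suite and acceptance script use sizes chosen to keep a full run
around a minute on one CPU while leaving no property under-sampled:
oracle-equivalence checks on frames up to 32×32 at tolerance 1e-10;
blur-ladder monotonicity over σ ∈ {0, 0.5, 1, 2, 4, 8} on 20 seeded
phantoms; band separability over 50 phantoms per band; gamma pair-counting
on 100 random tables; calibration-vs-brute-force on labeled sets up to 30
scores; and the held-out accuracy experiment on 100 phantoms per band at
256×256 (50 train / 50 test per band). Support comparisons in clip
reduction use a 1e-12 slack so `min_support = 1.0` is attainable under
floating-point summation of band fractions.

## Known limitations

Single-scale first-order filters cannot distinguish defocus from genuinely
structureless mucosa; a clean but featureless wall scores low. Calibration
transfers poorly across endoscope models or processors — thresholds are
device-conditional and should be refit per source. The out-of-body
heuristic is tuned to the generator's two frame classes. Video containers
are ingested as directories of still frames; decoding MP4/AVI to frames is
left to external tooling (e.g. ffmpeg) upstream of `read_frames()`.
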