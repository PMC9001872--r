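# lumiqc

Machine scoring of colonoscopy luminal visualization quality.

Clear visualization of the colonic lumen and mucosa is a prerequisite for a
high-quality colonoscopy, but human ratings of image quality are subjective
and vary between observers. `lumiqc` scores that quality objectively: every
video frame receives a no-reference sharpness score from a steerable
Gaussian-derivative filter bank (the **SFIL** focus measure), calibrated
thresholds map the score onto the four-point ordinal scale clinicians use
(1 = poor, 2 = almost poor, 3 = almost good, 4 = good), per-frame bands are
reduced to a clip-level estimate, and agreement with human raters is
quantified with ordinal statistics. It is aimed at endoscopy quality /
image-analysis researchers who want a transparent, fully testable baseline
rather than a learned black box.

## The method

**SFIL focus measure.** For a luminance frame $I$ and an isotropic Gaussian
$G_\sigma$, the filter steered to orientation $\theta$ is
$\cos\theta\, G_x + \sin\theta\, G_y$, with $G_x, G_y$ the first partial
derivatives of $G_\sigma$. With responses $R_{\theta_k} = I * (\cos\theta_k
G_x + \sin\theta_k G_y)$ at $\theta_k = k\pi/K$, $k = 0..K{-}1$ (default
$K = 4$, $\sigma = 1$ px), the frame score is

$$\mathrm{SFIL}(I) = \operatorname{mean}_{(x,y)\,\in\,\text{interior}} \; \max_k \left| R_{\theta_k}(x, y) \right|,$$

the mean taken over the frame interior (a border margin of
$\lceil 3\sigma \rceil$ px is excluded). Crisp in-focus edges give large
oriented derivative responses, so the score rises with focus; it is exactly
0 on a constant frame and linear in intensity.

**Calibration.** Three thresholds $t_1 < t_2 < t_3$ partition the score
axis into the four bands (scores on a threshold go to the higher band).
`fit_thresholds()` finds the triple maximizing classification accuracy on
labeled reference images by an exact search over candidate cut-points.

**Clip estimation.** `score_clip()` scores every frame and flags bright,
structure-free out-of-body frames; `estimate_clip_band()` reports the
shortest contiguous band interval (at most three bands) covering at least
`min_support` (default 0.8) of the valid frames — a single band, a range
such as "almost good to good", or no estimate.

**Agreement statistics.** Goodman–Kruskal gamma
$G = (C - D)/(C + D)$ over concordant/discordant observation pairs with a
normal-approximation test, an exact (sign-flip enumeration) Wilcoxon
signed-rank test for paired ordinal ratings, band-difference tables, and
match percentages between clip estimates and human ratings.

Since no clinical video can ship with the package, a synthetic generator
produces endoscopy-like phantoms — dark radial lumen, curvilinear vessel
edges, specular highlights — at four controlled blur levels
(σ = 6, 3, 1.5, 0.5 px for bands 1–4), plus out-of-body frames and paired
rater ratings with controlled agreement.

## Worked example

```r
library(lumiqc)

# sharp ("good") vs heavily blurred ("poor") phantom, same scene seed
sfil_score(generate_phantom_frame(phantom_spec(band = 4, seed = 1)))
#> <focus_score> sfil(sigma=1, n_orientations=4) = 0.0216086
sfil_score(generate_phantom_frame(phantom_spec(band = 1, seed = 1)))
#> <focus_score> sfil(sigma=1, n_orientations=4) = 0.00468115

# calibrate thresholds on 12 labeled phantoms per band
labeled <- do.call(rbind, lapply(1:4, function(band) {
  data.frame(score = sapply(1:12, function(i) sfil_score(
    generate_phantom_frame(phantom_spec(band = band, seed = band * 1000 + i)))$value),
    band = band)
}))
model <- fit_thresholds(labeled)
model
#> <calibration_model> measure=sfil thresholds=(0.00648106, 0.0124459, 0.0191542)
#>   n=48 (per band: 12/12/12/12), training accuracy 1.000

# a clip alternating bands 3 and 4 yields a two-band range estimate
clip <- generate_clip(rep(c(3L, 4L), 15), spec_defaults = phantom_spec(4, seed = 99))
estimate_clip_band(score_clip(clip, model), min_support = 0.9, min_valid_frames = 10)
#> <clip_estimate> clip_0001: almost good to good (range; support 1.00 over 30 valid frames)

# rater agreement on 412 simulated rating pairs
pairs <- generate_rating_pairs(412, seed = 1)
goodman_kruskal_gamma(crosstab(pairs))
#> <gamma_result> G = 0.812 (C = 47568, D = 4923, n = 412), z = 15.727, p = < 2.22e-16
```

The first two scores show blur suppressing the oriented-derivative energy
by a factor of ~4.6; the calibrated thresholds separate the four phantom
score distributions perfectly at this frame size; the clip estimate spans
exactly the two bands present in the profile; and the simulated rater pair,
which disagrees by at most one band ~95% of the time, shows the strong
positive rank association the gamma statistic is designed to detect.

A thin CLI over the same functions ships at
`system.file("cli", "lumiqc.R", package = "lumiqc")` with subcommands
`simulate-frames`, `simulate-ratings`, `score-frame`, `calibrate`,
`score-clip`, `agree`, `run-all`.

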