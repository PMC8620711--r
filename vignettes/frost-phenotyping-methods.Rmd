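---
title: "Methods: RGB frost-injury phenotyping from canopy coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RGB frost-injury phenotyping from canopy coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frostpheno)
```

## The measurement model

Freezing injury in young winter wheat expresses as loss of green canopy:
frost-killed tissue desiccates and bleaches, so the fraction of ground area
covered by living (green) blades — the vegetation coverage, VC — drops with
injury severity. `frostpheno` estimates VC from a single nadir RGB
photograph per plot (several photographs averaged per plot) and converts it
to an ordinal frost grade.

The estimator rests on three assumptions:

* **Color separates tissue classes.** Living blades are green-dominant,
  soil is red/brown-dominant, and withered tissue is yellow-to-white.
  Chromatic (sum-normalized) coordinates remove most brightness variation,
  and the excess-color indices ExG = 2g − r − b, ExR = 1.4r − g and their
  difference ExV = ExG − ExR push the classes apart: green canopy has
  strongly positive ExV, soil and withered tissue negative.
* **Illumination is roughly controlled.** Acquisition happens under a
  narrow light band (nadir view, midday); the pipeline does no white-balance
  or shadow correction. Strong specular reflection or deep shadow will leak
  between classes.
* **Coverage is a proxy, not a diagnosis.** Grading thresholds are
  coverage intervals; anything else that thins the canopy (drought,
  late sowing) shifts the grade the same way.

## Segmentation

`segment()` composes: chromatic normalization → ExV → 8-bit gray rendering
→ Otsu threshold → binarization → mask cleaning.

**Gray rendering.** ExV is mapped affinely from its fixed theoretical range
[−2.4, 3] onto [0, 255] (half-up rounding). Using the fixed range, rather
than per-image min/max, makes a given gray level mean the same ExV in every
image, so thresholds are comparable across a batch. ExV = 0 lands at gray
113.

**Otsu's threshold** maximizes the between-class variance
σ²\_b(t) = w₀w₁(μ₀ − μ₁)² between classes {level ≤ t} (background) and
{level > t} (plant). Numerical conventions, chosen for determinism:

* candidate thresholds span the occupied gray range, so a degenerate
  single-level histogram returns that level;
* ties break to the smallest maximizing t;
* the upper class is plant (higher ExV = greener).

**Threshold floor.** The effective threshold is
`max(otsu_t, gray(ExV = 0))`. Otsu always splits a histogram, even a
vegetation-free one; without the floor an all-soil image would return ~50 %
spurious "plant". Requiring positive excess vegetation is physically
motivated and costs nothing on real canopies, where the plant mode sits
well above ExV = 0. The floor is exposed as `min_gray` in
`segment_params()` (set 0 to disable).

**Mask cleaning** removes 8-connected components smaller than
`min_object_px` (default 16 px — smaller than any blade at the default
scene scale, larger than salt noise) and fills enclosed background holes
(default on; blade crossings trap small soil holes that are visually
canopy). Cleaning is idempotent. Component analysis uses EBImage's
labeling, with diagonal-touching labels merged to give true
8-connectivity.

**Degenerate inputs.** Pure-black pixels (R+G+B = 0) take r = g = b = 0 by
convention, giving ExG = ExR = ExV = 0 — classed as background by the
floor. This avoids 0/0 without special cases downstream.

## Coverage and grading

Coverage is the exact plant-pixel percentage of the image. Grades partition
[0, 100] totally and monotonically:

| grade | label | coverage |
|-------|------------------|----------------|
| 1 | no obvious injury | VC ≥ 15 % |
| 2 | slight | 10 ≤ VC < 15 |
| 3 | severe | 5 ≤ VC < 10 |
| 4 | most severe | VC < 5 |

Two design points were genuinely open and decided here:

* **Numbering direction.** Field practice reads grade 1 as the lightest
  injury (the best genotypes), so the default `"severity"` mapping assigns
  grade 1 to the highest-coverage interval. The reversed list-order
  numbering is available as `mapping = "literal"` for compatibility with
  records that count the intervals upward from low coverage.
* **Boundary inclusivity.** The interval edges 5/10/15 % go to the
  less-severe grade (15 % → grade 1), making the mapping total; with
  continuous coverages the choice is measure-zero but must be fixed for
  determinism.

Plot-level coverage is the arithmetic mean over the plot's images (equally
exposed, equally weighted), and the grade is recomputed on the mean rather
than averaged over per-image grades — grades are ordinal, not metric. Both
image- and plot-level tables are reported, since either aggregation level
may be wanted for variety comparison.

## Withered-leaf extraction

Withered tips are detected in HSI space (classical geometric transform:
I = (R+G+B)/765, S = 1 − 3·min(r,g,b), arccos hue reflected when B > G;
H = 0 for achromatic pixels). A pixel is withered when

* 40° ≤ H ≤ 75° and I ≥ 0.35 (yellowed tissue), or
* S ≤ 0.15 and I ≥ 0.7 (bleached white).

These four numbers are calibration defaults chosen against the generator's
withered palette and a margin to soil hues (brown sits near H ≈ 30° with
S ≈ 0.5); all are exposed in `withered_thresholds()` because field scenes
with specular highlights or pale bud color can need adjustment. Withered
pixels are disjoint from coverage by construction — ExV of yellow-white
tissue is at or below zero, so it segments as background — mirroring the
rule that frozen tissue does not count as living canopy.

## The synthetic generator

`generate_scene()` emulates exactly the features the estimator relies on:

* green blades as oriented elongated strips, clustered into `n_rows = 6`
  horizontal bands (the sowing rows of a 1.5 × 1.5 m plot at 25 cm
  spacing);
* textured brown soil (palette patches plus low-frequency value noise);
* optional withered tips: the far `withered_tip_fraction` of each blade's
  pixels recolored from a yellow-white palette and excluded from the plant
  truth;
* a global illumination factor drawn from 1 ± 0.04 (a narrow
  controlled-light band) and per-channel Gaussian sensor noise
  (sd 2 gray levels).

Blades are added until the green coverage first reaches the target; no
single blade may push it more than 0.5 points past, so the true coverage
lies in [target, target + 0.5]. Pixel membership is hard (no
anti-aliasing), so the truth masks and `true_coverage_pct` are exact by
construction, and scenes are byte-identical for equal seeds.

What the generator does **not** model — and hence what passing tests do not
demonstrate about field data: mixed illumination and shadows, specular
reflection, weeds and straw with vegetation-like color, motion blur,
perspective distortion, overlapping canopies at high density, and soil
whose color approaches the withered palette. The default palettes give a
blade/soil ExV separation well above 0.5; recovery guarantees hold for
scenes in that separable regime, not for arbitrary imagery.

## Problem sizes and runtime choices

The test suite and the acceptance script use 320 × 320 px scenes (102 400
pixels), 50 scenes for the coverage-recovery sweep (targets 2/5/8/12/18 %,
10 seeds each), 200 random histograms for the Otsu oracle comparison, and
small 2–3 variety layouts for end-to-end batch runs — sizes at which the
full suite completes in well under a minute while every stage is exercised
at realistic per-image scale. The full default design (768 plots, 2304
images) is validated count-wise in closed form; emitting all 2304 PNGs is
supported (`generate_experiment(default_layout(), ...)`) but not done in
the tests.

## Known limitations

* Coverage confounds frost injury with any other cause of thin canopy;
  grades are screening scores, not physiological measurements.
* The withered detector inherits HSI's instability near achromatic pixels;
  very dark or very bright soils can enter the white branch.
* No instance separation: touching plants are one component, so contour
  counts are not plant counts.
* The Otsu floor assumes the ExV rendering; thresholding ExG instead
  (`index_kind = "ExG"`) uses the analogous ExG = 0 floor but has weaker
  red suppression on bright soils.
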