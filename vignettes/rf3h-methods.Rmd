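---
title: "Methods: quantifying rF3H imaging assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying rF3H imaging assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rf3h)
```

## The measurement model

An rF3H experiment reads out RNA–protein binding as red-fluorescence
enrichment at a nuclear structure where a green-tagged RNA trap has
anchored the test RNA. The per-cell statistic is

$$\mathrm{ratio} \;=\;
\frac{\overline{R}_{\mathrm{anchor}} - \overline{R}_{\mathrm{nucleus}}}
     {\overline{G}_{\mathrm{anchor}} - \overline{G}_{\mathrm{nucleus}}},$$

with $\overline{R}$, $\overline{G}$ arithmetic mean gray values of the red
(protein) and green (trap) channels over the anchor region and over the
*whole* nucleus. Two properties follow directly and are enforced by tests:

* **Offset invariance.** Any additive constant in either channel cancels in
  the differences, so camera offsets and uniform backgrounds never need to
  be subtracted.
* **Scale equivariance.** Multiplying the red channel by $c>0$ multiplies
  every ratio by $c$; because every condition of one experiment is imaged
  identically, the factor cancels when ratios are divided by the control
  group's mean. Detector gain therefore drops out of the reported fold.

The reference region is deliberately the whole nucleus *including* the
anchor pixels: "whole nucleus" is read literally. This choice is
self-consistent: if the anchor occupies fraction $f$ of the nucleus, both
the red and the green excess acquire the same factor $(1-f)$, which cancels
in the ratio. For the same reason the statistic is robust to moderate
over- or under-sizing of the detected anchor mask: with near-uniform
structure profiles, a mask covering a fraction of the true anchor dilutes
numerator and denominator equally.

Raw ratios may be negative (a red dip at the anchor); they are kept, not
clipped, because clipping would bias group means upward.

### Normalization and statistics

Each cell's ratio is divided by the arithmetic mean ratio of the QC-passing
cells of the designated no-RNA control group. The divisor is the mean, not
the median, to match the assay's use of arithmetic means throughout; the
control group's normalized mean is consequently exactly 1. Normalization
requires at least 3 usable control cells and a strictly positive control
mean; both violations are hard errors rather than silent NAs, since every
downstream number would be meaningless.

Group comparisons use the two-sided pooled-variance Student's t-test
($df = n_a + n_b - 2$), with a Welch option behind a flag that is off by
default, and the conventional star annotation (`*` < 0.05, `**` < 0.01,
`***` < 0.001). No multiple-testing correction is applied; comparisons
against the control are reported marginally, mirroring how such figures are
conventionally annotated. Group summaries report the arithmetic mean and
the sample standard deviation ($n-1$); the SD of a single-cell group is
undefined and reported as `NA`.

## Segmentation and anchor detection

Nucleus partitioning is deterministic: Gaussian smoothing (default
$\sigma = 2$ px) → Otsu threshold on the range-normalized image → hole
filling → connected-component labelling → removal of components outside
the admissible area (default 300–8000 px²) or touching the image border.
Range normalization before Otsu makes the partition invariant to affine
intensity transforms $aI + b$ ($a > 0$) of the stain channel. Touching
nuclei are not split; a merged blob typically exceeds the area bound and is
discarded, which loses cells but never corrupts measurements.

Anchor detection depends on the configured geometry:

* **single_spot** — a Laplacian-of-Gaussian filter at scale
  `spot_sigma_px` (default 3 px, matching a spot of radius
  $\approx \sigma\sqrt2$) is evaluated inside the nucleus; the
  maximum-response pixel wins, with ties broken first by disk-integrated
  intensity and then by lowest (row, col) so the result is fully
  deterministic. The anchor mask is the disk of radius $\sigma\sqrt2$
  around the peak, clipped to the nucleus.
* **multi_puncta** — all local maxima of the LoG response that pass the
  acceptance rule are pooled into one mask; per-punctum statistics are not
  emitted because enrichment is reported per cell.
* **nuclear_rim** — the nucleus minus its morphological erosion by the
  band width (default 4 px); a purely geometric construction with no
  intensity threshold.

A spot or punctum is accepted only if its smoothed intensity exceeds the
nuclear median green level by a relative margin (`detect_threshold`,
default 0.5, i.e. 50% brighter). A uniform green nucleus therefore yields
an empty anchor and the cell is QC-flagged (`no_anchor`) instead of
producing a meaningless ratio. Cells whose green excess at the anchor does
not exceed 5% of the nuclear green mean (`denom_floor_frac`) are flagged
`weak_trap`: the denominator of the ratio would be dominated by noise. The
floor is relative, not absolute, so no assumption about intensity units is
made.

Both convolutions (Gaussian and LoG) are applied as cached separable
banded-matrix products with replicate boundary handling — exact,
platform-stable arithmetic with no FFT wraparound.

## The synthetic experiment generator

Because the assay's original microscopy images are not publicly deposited,
the package ships a generator that emulates the experimental designs and
gives every stage a ground truth. One nucleus is rendered per field
(96 × 96 px by default): an ellipse with uniformly drawn semi-axes
(20–28 px), a green channel with a per-cell diffuse trap level plus the
anchor structure at `trap_gain` (default 4) times that level, and a red
channel with a per-cell diffuse level plus recruitment at the anchor.

The recruitment model is multiplicative on the *nonspecific excess*: red
inside the anchor is $r\,(1 + (g_0 - 1)\,G)$, where $g_0 = 1.15$ is the
nonspecific gain every condition shows (controls exhibit small but nonzero
enrichment, so control normalization is well defined) and $G$ is the
condition's binding fold (1 for controls). Under this parameterization the
expected raw ratio is

$$E[\mathrm{ratio}] \;=\;
\frac{\bar r\,(g_0 - 1)\,G\,(1-f)}{\bar g\,t\,(1-f)}
\;=\; \frac{\bar r\,(g_0-1)\,G}{\bar g\, t},$$

so the anchor fraction $f$ cancels, the expected *normalized* enrichment
equals $G$ exactly, and doubling $G$ doubles it. (An alternative
parameterization that multiplies the whole gain by $G$ would make the
normalized expectation a nonlinear function of $G$; linearity in the
configured fold was chosen so preset folds are directly interpretable as
the expected reported enrichment.)

Per-cell red and green diffuse levels are log-normal with **fixed mean**
(the log-mean is shifted by $-\sigma^2/2$), emulating cell-to-cell
expression variability; because the spread is mean-preserving, group means
of normalized values are invariant to the spread up to Monte-Carlo error.
Defaults: red `expr_sdlog` 0.3 and green `diffuse_sdlog` 0.2, giving
per-cell ratio CVs around 35–40%, comparable to the spread such assays
show in per-cell scatter plots.

Camera noise is a constant offset (100 a.u.) plus Gaussian noise with
signal-dependent variance (`poisson_slope` 0.5 per intensity unit,
approximating shot noise) and additive read noise (SD 8 a.u.). An optional
Gaussian optical blur exists but defaults to 0: blurring bleeds
nuclear-interior intensity across the boundary, which depresses the
whole-nucleus reference means and shifts the measured enrichment away from
the closed-form expectation that the oracle tests rely on; the noise-only
model keeps the generative region means exact. With noise disabled
entirely, the rendered images are piecewise constant and pipeline ratios
reproduce the analytic expectation to floating-point accuracy — the
strictest oracle in the test suite.

Figure-design presets freeze the geometry, the per-group cell counts and a
binding fold equal to the enrichment each quantified experiment reported:
`F1_pp7_PCP` (single spot, n = 23/24, fold 2), `F2_polyA_PABPC1`
(single spot, 27/27, fold 2), `F5_laminB1_rim` (rim, 21/24, fold 2),
`F5_chromocenter_MCP` (multi-puncta, 23/26, fold 3), `F6_dCas13a_MCP`
(single spot, 21/26, fold 2); each has a matched null variant with all
folds at 1. The chromocenter preset detects at `spot_sigma_px = 2` to
match its smaller puncta (radius 2.5 px).

### What the generator does not emulate

No point-spread-function optics beyond the optional single Gaussian blur,
no cytoplasmic compartment (fields contain exactly one nucleus on a dark
background), no photobleaching, no z-dimension or time, no touching or
overlapping nuclei, no spatially structured background. Consequently,
passing recovery tests demonstrates that the pipeline's arithmetic,
detection and normalization are correct under the stated generative
assumptions — not that segmentation would survive crowded fields or heavy
optical aberration in real data.

## Verification design and problem sizes

* **Oracle equivalence** (exact): noise-free simulation with ground-truth
  masks injected must reproduce the analytic per-cell ratios to 1e-9
  relative error, for all three geometries.
* **Parameter recovery** (stochastic): each figure preset is simulated and
  analyzed end-to-end; the specific condition's normalized mean must land
  within ±15% of the preset fold. A single experiment at the preset cell
  counts carries a Monte-Carlo standard error of roughly 13% on that mean
  — dominated by the per-cell expression variability the generator
  deliberately includes — so the recovered enrichment is estimated as the
  mean over 8 replicate experiments (standard error under 5%), with
  replicate seeds derived from one fixed base seed. The per-experiment
  spread itself is part of the emulated biology, not something to
  suppress in the generator.
* **Null calibration** (stochastic): 200 simulated null experiments
  (matched null preset, fold 1) must yield a Student's-t rejection rate at
  $\alpha = 0.05$ inside [2.5%, 7.5%]. These replicates measure with
  ground-truth masks injected — the criterion calibrates the statistics
  stage, and skipping 200 redundant segmentation passes keeps the suite
  fast; noise and expression variability remain active.
* **Monotonicity** (stochastic): the estimated enrichment over folds
  {1, 1.5, 2, 3} at n = 25/condition, each averaged over 5 replicates,
  must be strictly increasing.
* **Segmentation quality**: on the default noise preset, every simulated
  nucleus must be recovered with IoU ≥ 0.9 against its true mask, and
  every detected spot centroid must lie within 2 px of the true center.

## Numerical and formatting choices

* Images are written as plain multi-page 16-bit grayscale TIFFs (one page
  per channel, order: stain, green, red) with the channel-role mapping in
  the run manifest rather than embedded metadata; integer gray values
  round-trip exactly. Writing quantizes to integers — the one lossy step,
  irrelevant at the simulator's intensity scales (quantization error
  ≤ 0.5 a.u. against signals of hundreds).
* Masks are boolean matrices congruent with the image grid; coordinates
  are 1-based (row, col) as is idiomatic in R.
* The manifest validator rejects unknown keys outright, so misspelled
  parameters can never silently fall back to defaults; analysis, I/O and
  control-group failures raise distinct condition classes that the CLI
  maps to distinct exit codes.
* Per-cell CSVs write doubles at full precision; a write–read cycle
  preserves at least 12 significant digits.
* All segmentation and measurement stages are deterministic; the only
  randomness anywhere is the simulator's seeded RNG, and simulation
  restores the caller's RNG state.

## Known limitations

Touching nuclei are merged and usually discarded by the area filter rather
than split by watershed. The single-spot rule always returns at most one
blob — cells with several bright green foci (e.g. multiple integration
arrays) contribute only their dominant spot, a deterministic convention
rather than a biological claim. The whole-nucleus reference is carried
over to the rim and puncta geometries by analogy with the single-spot
design. Real acquisition noise and background levels for this assay are
unreported; the preset noise parameters are plausible defaults, not
calibrated values.
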