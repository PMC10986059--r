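---
title: "Quantifying choroidal vascularity and choriocapillaris perfusion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choroidal vascularity and choriocapillaris perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chorovasc)
```

# The measurement problem

The choroid is the vascular bed between Bruch's membrane (BM) and the
sclera. Its medium and large vessels (Sattler and Haller layers) appear in
structural OCT B-scans as dark lumens inside a brighter stromal matrix; the
innermost capillary sheet, the choriocapillaris, is too fine for structural
imaging and is instead assessed from en-face OCT angiography as the
fraction of the field *lacking* flow signal. Studies of near-work responses
track six scalar metrics per eye and visit: SFCT (µm), LA, SA, TCA
(10³ µm²), CVI (%) and CcFD (%).

`chorovasc` implements the full path from images to cohort statistics. The
segmentation of the choroid's boundaries is deliberately an *input*
(upstream deep-learning segmenters produce it); everything after that —
binarization, area accounting, magnification correction, artifact
compensation, thresholding, statistics — is implemented and tested here.

# Structural track

## Choroid band convention

A boundary pair (`upper`, `lower`) defines the band of column *j* as the
half-open pixel run `(upper[j], lower[j]]`. With this convention the band
height in pixels equals `lower − upper`, so a 300-µm-thick band at
3 µm/px contributes exactly 100 rows and SFCT = `(lower − upper) ×
axial spacing` is consistent with the area accounting (a 6 mm × 300 µm
rectangular band yields TCA = 1800 × 10³ µm² exactly). The ROI covers the
half-open column interval `[fovea − w, fovea + w)` with
`w = round(3 mm / corrected lateral spacing)`; rounding is to the nearest
column.

## Masked Niblack binarization

The per-pixel threshold is `T = mean_W + k · SD_W` over a square window
*W*, with both statistics restricted to pixels inside the band mask
(integral-image implementation, O(n)). Pixels strictly below `T` are
lumen; **ties are stroma**. The tie rule is fixed so that a constant image
yields an empty lumen mask for any `k ≤ 0` and tests can assert exact
masks. The rule is scale-invariant: multiplying the image by any positive
constant scales mean and SD equally and leaves the mask unchanged.

Defaults are the classic Niblack setting `k = −0.2` with a 51-px window
(≈ 0.3 mm laterally at 5.86 µm/px). These are *assumptions*: the
literature that fixes them for choroid work does not print them uniformly,
so both are exposed in `niblack_params()` and in the pipeline config.
A 3×3 median despeckle (`despeckle()`, radius 1) precedes binarization in
the quantify stage, mirroring the despeckle step of published CVI
protocols; `niblack_binarize()` itself is pure so its contract stays
testable in isolation.

Local thresholding carries one structural caveat: a window that contains
only one tissue class places its threshold *inside* that class and
misclassifies about half of it. On real choroid this is rare — lumens are
separated by vessel-wall septa, so stroma is interstitial everywhere — and
the synthetic generator reproduces exactly that property (below). At the
defaults, windows virtually always straddle both classes.

## Magnification correction

Only the lateral scale depends on eye length. We use Bennett's abbreviated
factor `q ∝ AL − 1.82 mm`: the corrected lateral spacing is the nominal
spacing × `(AL − 1.82)/(AL_ref − 1.82)`, with the device-assumed
`AL_ref = 24.385 mm` configurable. Axial spacing is taken as
AL-independent. Consequence: areas are *physical* — the same tissue
measured in a longer eye yields the same TCA (to column rounding), because
the per-pixel area grows while the ROI pixel count shrinks.

## Meridian averaging

Metrics are computed per meridian and then averaged arithmetically —
including CVI, i.e. the mean of the per-meridian ratios rather than the
ratio of pooled areas. The pooled alternative was rejected because the
stated procedure averages *estimates by meridian*; for nearly equal TCA
between meridians the two differ negligibly, but the mean-of-ratios
reading is the literal one and keeps `average_meridians()` a pure
field-wise mean.

# Perfusion track

## Slab and threshold semantics

The choriocapillaris slab runs from the BM surface to 20 µm below it
(`slab_spec()`); `project_cc_slab()` averages the volume over that depth
run. The deficit rule is an **absolute** cut on the compensated 8-bit
image: deficit iff intensity < `multiplier × sigma_ref`, defaults 1.5 × 30
= 45 gray. `sigma_ref` is the mean SD of a normative database of young
healthy eyes; since any device's database is proprietary, it is a config
value, never hard-coded into results. CcFD is reported over the pixels
whose *centres* fall inside a 2.5-mm circle (sized in
magnification-corrected units) — no anti-aliased partial pixels, so counts
are integral and tests exact. The discrete count matches π(d/2)² to well
under 1% for ≥ 256-px fields.

## Artifact compensation

The published compensation algorithms for shadowing and projection are not
restated in enough detail to clone, so `compensate_enface()` implements a
functional surrogate validated only against the synthetic generator's
ground truth:

* **Shadowing** — divide by the smoothed (Gaussian, σ = 15 px)
  co-registered inner-retina reference normalized to its global median. An
  overlying opacity attenuates slab and reference alike, so the division
  restores the slab signal; noise in the shadowed region is amplified by
  the same factor, which is why compensation matters most when the shadow
  is deep enough to push perfused tissue under the 45-gray threshold
  (attenuation ≲ 0.25 at the default gray levels).
* **Projections** — pixels under the projection mask are replaced by the
  median of the surrounding non-projection pixels within a ±6 px ring.

Compensation runs *before* thresholding (the order is unstated upstream;
compensate-first is the only order in which the absolute threshold sees
artifact-free intensities).

# Synthetic data: what it emulates and what it does not

`generate_bscan_scene()` emulates a 12-mm radial line scan (2048 A-scans,
5.86 µm/px lateral, 3 µm/px axial) through a choroid band of smoothly
varying thickness. Lumens are axis-aligned ellipses on a jittered
hexagonal lattice whose rows follow the band; nominal radii grade from
`vessel_radius_range_um[1]` at the inner side to `[2]` at the scleral side
(Sattler → Haller), with ±15% per-vessel size jitter and positional
jitter. The lattice dilation is calibrated (≤ 200 deterministic re-draws)
until the realized lumen fraction is within ±0.05 of the target; targets
above 0.85 are rejected as geometrically unreachable for packed lumens
with interstitial stroma. The hexagonal layout was chosen over unrestricted
random placement because overlapping random ellipses coalesce, at high
vascularity, into lumen "lakes" larger than any local-threshold window —
a geometry real choroid never shows (lumens are separated by vessel
walls) and under which *no* threshold rule can meet a 2.5-pp recovery
tolerance. Packing with septa preserved is both the anatomically faithful
choice and the one under which local thresholding is well-posed.

Speckle is multiplicative gamma noise. `speckle_shape = 4` is the
single-frame model; the device averages 64 registered frames per line, and
the rendered image is that average — the mean of *n* iid Gamma(s, s)
multipliers is Gamma(ns, ns), so the effective shape is
`speckle_shape × n_frames` (256 by default, ≈ 6% intensity CV). Ground
truth (masks, areas, CVI, SFCT) is computed by pixel counting *before*
noise and 8-bit quantization.

`generate_cc_enface()` renders a 3 mm × 3 mm, 512-px field: perfused
texture (180 ± 5 gray) with elliptical deficit blobs (5 gray) re-drawn
until the in-circle deficit fraction is within ±0.02 of target, plus an
optional circular shadow (multiplicative attenuation, recorded as a map)
and bright near-vertical projection stripes copied into a synthetic
inner-retina reference.

`generate_cohort()` draws per-subject baselines from the two cohorts'
baseline distributions and adds per-duration changes at the reported
means/SDs (non-significant cells: zero mean, typical SD). Baselines are
drawn once per subject and reused as the pre value of every visit; the
simulator models metric-level statistics only, so simulated LA + SA does
not reproduce TCA row-wise (each metric is drawn independently) and CVI is
not the ratio of the simulated areas. Tests that need the additivity
invariant use the imaging track, where it holds exactly.

What the generator does **not** model: wave-optics speckle correlation,
3-D vascular topology, motion/blink artifacts, partial-volume gray levels
at vessel walls, and diurnal or accommodation-state covariates. Passing
recovery tests therefore demonstrate correctness of the *quantification*
given clean segmentation and first-order noise, not robustness to every
artifact of clinical data.

# Statistical layer

* `percent_change()` is anchored on the pre value: `100 (post − pre)/pre`.
* `paired_change_test()` is the one-sample t on change scores;
  `bonferroni_adjust(p, m)` multiplies by the number of comparisons
  actually performed (the pipeline records `m`).
* `rm_anova_gg()` computes the within-subject F and Box's epsilon from the
  sample covariance of the k levels, clamped to `[1/(k−1), 1]`; both df
  are multiplied by epsilon. Degenerate inputs are defined: k = 2 gives
  epsilon = 1 exactly; data constant over time give F = 0, p = 1; a zero
  error variance with a non-zero time effect is an error.
* `group_contrast_ancova()` replaces the original generalized estimating
  equations with a linear model `change ~ group × duration + AL`
  (duration sum-coded, so the group coefficient is the AL-adjusted mean
  difference averaged over durations) with cluster-robust (sandwich)
  variance by subject. With one observation per subject-duration and a
  cohort-level contrast, this targets the same estimand as a GEE with
  exchangeable working correlation; the full GEE machinery (working
  correlation/link selection, which the source does not specify) is out of
  scope. Zero-variance AL drops the covariate with a warning.
* `icc_absolute_agreement()` is ICC(A,1) from two-way ANOVA mean squares;
  `bland_altman()` reports bias ± 1.96 SD of differences.
* Shapiro–Wilk normality screening is computed and reported per cell in
  the analysis stage but never gates anything, keeping runs deterministic.

# Pipeline and reproducibility

`run_config()` validates every sub-config up front; `run_simulate()`
writes images, JSON truth sidecars, the cohort CSV and a manifest listing
every file with its derived seed plus the MD5 of the config actually used;
`run_quantify()` fails fast, naming any missing file; `run_analyze()`
writes the change-test table (direction, Bonferroni-adjusted significance),
the duration ANOVA, the group contrasts and a plain-text trend report.
One master seed drives everything: re-running a config reproduces every
CSV byte for byte. The CLI wrapper (`inst/cli/chorovasc`) adds nothing but
argument parsing.

# Problem sizes used by the test suite

Unit tests run on shortened scan lines (500–1200 px, 2–3 mm ROI) to keep
the suite fast; the acceptance layer exercises the full acquisition
geometry: 20 full-size scenes spanning true CVI 45–75% (CVI error
tolerance 2.5 pp, TCA 2%), 20 angiograms at 2–20% deficit (1.5 pp), 20
shadow scenarios (attenuation 0.10–0.25), 2000 null replicates for type-I
error, 500 for power, and n = 500 for the ICC variance-components check.
These sizes are the package's choices for stable Monte-Carlo estimates at
interactive runtimes.

# Known limitations

* Niblack window/k defaults are field conventions, not device-documented
  values; sensitivity to them should be checked on real data.
* The artifact compensation is a surrogate validated on synthetic truth
  only; device-specific compensation may differ.
* The cohort simulator draws metrics independently (no LA/SA/TCA
  correlation structure, no pre-value measurement error across visits).
* Sub-pixel vessels (< ~2 px across) are below the resolution of both the
  generator's rasterization and the despeckle step; the defaults keep all
  vessels comfortably resolvable.
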