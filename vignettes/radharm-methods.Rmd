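---
title: "Methods: multi-centre radiomics variability, normalisation and harmonisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-centre radiomics variability, normalisation and harmonisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in `radharm`,
the assumptions behind them, the parameters that matter, and the numerical
and design choices made where the field leaves them open. It states no
empirical result beyond what the package's own tests and
`scripts/acceptance.R` compute.

## The scientific setting

Magnitude MR images carry no standardised intensity scale: the same
myocardium can be stored as values near 300 at one centre and near 14,000 at
another, with different effective contrast (receiver gain, coil profile,
vendor reconstruction). Radiomic texture features computed from discretised
gray levels inherit this variability. The package implements the two
families of countermeasures in routine use — image-level intensity
normalisation and feature-level statistical harmonisation — together with
the instruments needed to judge them: a distribution-similarity index and
two classification protocols that measure, respectively, how much *centre*
signal and how much transferable *disease* signal a feature set carries.

## The synthetic cohort generator

Real multi-centre cardiac cohorts cannot ship inside a package, so every
stage is exercised on a generator whose statistical structure mirrors one.

**Anatomy.** Each study is a 3-slice short-axis phantom in a 64 mm field of
view: an LV cavity disc, a concentric myocardial ring and an RV crescent,
with per-subject Gaussian variation of cavity radius (8 ± 1 mm at
end-diastole) and wall thickness. The hypertrophic (HCM) class has mean wall
thickness twice the healthy mean (10 vs 5 mm) — the cardinal morphological
sign of the disease — and an altered myocardial texture: the stationary
Gaussian random field added to the myocardium has both larger standard
deviation (0.12 vs 0.06 on the canonical unit intensity scale) and a longer
correlation length (3.0 vs 1.5 mm), so second-order features have a genuine
spatial signal to detect, not just a histogram shift. End-systole shrinks
the cavities (×0.75) and thickens the wall (×1.25).

**Centre effects.** Studies are generated on a canonical `[0, 1]` intensity
scale and pushed through a per-centre monotone acquisition transform
`raw = max_intensity · (gain · x^gamma + offset) + noise`. The five default
profiles spread `max_intensity` from 357 to 14,442 and in-plane pixel size
from 0.85 to 1.45 mm, matching the orders-of-magnitude disparity reported
for five clinical 1.5T scanners; `gamma` between 0.85 and 1.15 injects the
nonlinear contrast differences that simple rescaling cannot undo. The
default class counts per centre (healthy 14/11/33/32/22, HCM 15/5/37/24/25;
112 + 106 = 218 subjects) reproduce the clinical cohort's distribution. A
`null_effect` mode gives every centre the identical profile, so any
downstream centre discrimination would be spurious — this calibration is
tested.

**What the generator does not emulate.** Cine temporal dynamics, through-plane
anatomy, MR physics (bias fields, k-space artefacts), demographic covariates,
and HCM sub-phenotypes. Passing tests therefore demonstrate that the
*pipeline machinery* behaves correctly under controlled centre and disease
effects — not that any specific clinical accuracy is reproduced. The
injected disease effect is deliberately strong and clean so that the
qualitative orderings (raw vs normalised vs harmonised) are unambiguous at
desk scale; clinical accuracies live closer to the decision boundary.

## Geometry and resampling

Voxel arrays are indexed `[row, col, slice]` with spacing in mm per axis.
Resampling is in-plane only (slice thickness ~10 mm is left untouched, as is
conventional for short-axis stacks): bilinear for the image, nearest
neighbour for the categorical mask, on corner-aligned grids (sample `i` sits
at `(i−1)·d`). The interpolation kernel is not standardised in the
literature; linear is assumed and the grid convention is pinned down by a
brute-force oracle test. **Order matters**: studies are resampled *before*
normalisation and extraction. Resampling an ROI-normalised image would blend
raw-scale background into boundary voxels of the normalised ROI and explode
the discretised level count; `glcm()` guards against this failure mode
(error above 2000 levels).

## Normalisation methods

All four transforms are monotone (rank-preserving) within their fitting
scope, and each can be fitted/applied on the whole image or independently
per ROI (background untouched):

* `R` — min–max rescaling to `[0, 1]`. Idempotent.
* `N` — z-normalisation with the *population* (1/n) standard deviation.
  Idempotent, affine-invariant.
* `HM` — empirical quantile mapping onto one template subject's
  distribution, with linear interpolation between order statistics and
  mid-rank plotting positions; matching a sample to itself is the exact
  identity. The template defaults to the alphabetically first healthy
  end-diastolic study of the reference centre.
* `PLHM` (Nyúl–Udupa) — per-image percentiles on a grid (deciles flanked by
  1st/99th-percentile anchors) are mapped so the anchors hit the standard
  range `[0, 1]`, then averaged over the reference centre's studies to give
  standard-scale landmarks; application is the piecewise-linear map sending
  an image's own grid percentiles onto those landmarks, with end-segment
  linear extrapolation beyond the anchors.

The reference centre defaults to the one with most studies (Sagrada Familia
in the default cohort). The `[0, 1]` standard range keeps post-normalisation
bin counts at width 0.05 in the tens, the same regime as the raw images at
width 25. Degenerate inputs never abort a cohort run: constant regions map
to zeros (`R`, `N`) or the standard-range midpoint (`PLHM`) with a classed
warning.

## Feature panel and discretisation

Gray levels are `floor((x − min)/W) + 1` with the anchor at the per-ROI
minimum, making the level image shift-invariant; `W = 25` for raw images and
`0.05` after normalisation. Per ROI the panel is 18 first-order features
(moments and order statistics on raw intensities; entropy/uniformity on the
discretised histogram; kurtosis is uncorrected `m4/m2²`) and four texture
matrices — GLCM (24 features), GLRLM (16), GLSZM (16), GLDM (14) — giving
88 features × 3 ROIs. Shape features are excluded: they depend only on the
segmentation, not the intensities under study. Default extraction is 3D
(13 unique directions for GLCM/GLRLM, 26-connectivity zones, dependence
tolerance `alpha = 0`); a 2D in-plane mode exists for thin stacks. The same
discretisation is used for all families (per-family level optimisation is a
known refinement, deliberately out of scope). Column order is fixed — ROI
(LV, MYO, RV), family (firstorder, glcm, gldm, glrlm, glszm), alphabetical
feature — because the sequential correlation filter is order-dependent.
Every matrix builder is verified against an independently written
brute-force enumerator on hundreds of random small ROIs.

## ComBat harmonisation

The location/scale model assumes per-centre Gaussian features, which raw
radiomics rarely satisfies; a per-centre quantile transform onto the
standard normal (K = 20 quantile grid, linear interpolation, mid-rank ties)
is therefore applied first. ComBat then standardises each feature by its
grand mean and pooled SD over *all* subjects — the "virtual reference": no
centre is privileged — estimates per-centre means/variances of the
standardised values, and shrinks them towards cross-feature priors (normal
for location, inverse-gamma for scale, hyperparameters by method of
moments) with the standard iterative conditional update (tolerance `1e-4`,
cap 500 iterations). No covariates are modelled. Zero-variance features
pass through with a warning rather than aborting. Shrinkage is a convex
combination, so shrunk location effects never overshoot the naive
estimates; a second fit on adjusted data returns effects near zero. Both
properties are tested, and the adjustment is cross-checked against an
independent reference implementation on data where the two variants
coincide.

## Variability scoring

The sequential filter scans features in canonical order and drops any with
squared Pearson correlation ≥ 0.9 against an already-retained earlier
feature (fitted on healthy subjects, per ROI × phase × order block). For
each retained feature and unordered centre pair, the Jensen–Shannon
divergence is computed between the two centres' healthy-subject feature
distributions: shared equal-width bins over the pooled range (bin count =
max(10, Freedman–Diaconis)), additive smoothing `1e-10`, logarithms base 2
so the index is bounded in `[0, 1]`. The base is documented prominently
because the conventional similarity threshold τ = 0.01 is base-dependent.
Features count as "similar" under strict inequality `JSD < τ`.

**Small-sample caveat.** With 11–33 healthy subjects per centre, the
histogram JSD estimator has a strong positive bias (two finite samples from
the *same* distribution typically score ~0.2 at these sizes). On the
default synthetic cohort the clinical-scale τ = 0.01 is therefore never
reached and the %-below-τ summaries are 0; they become informative at
larger per-centre n or larger τ. The acceptance script reports them as
computed.

## Classification protocols

Random forests (500 trees, √p variables per split, unlimited depth — fixed
rather than tuned, for stable Gini importances) with balanced accuracy
(mean per-class recall) throughout, since neither classes nor centres are
balanced. *Centre identification*: healthy subjects, one feature order ×
one ROI at a time, stratified 5-fold CV; chance is 1/5 with five centres;
lower accuracy means less centre contamination. *Generalisation*: all
features from all ROIs, no prior feature selection, trained within a single
centre under class-stratified 5-fold CV repeated for 5 seeds; each fold's
model is evaluated on the pooled held-out-centre subjects (a per-centre
breakdown is also emitted; the aggregation is a documented choice).
Protocols fix their RNG seed before fold assignment, making reports
byte-reproducible. Both phases are generated and extracted; the
classification protocols use end-diastolic rows by default (which phase fed
the clinical classifiers is unstated; ED is the conventional reporting
phase), while variability summaries are per phase.

## Problem sizes and determinism

The default study — 218 subjects × 2 phases, 64 mm FOV at centre-specific
resolution, resampled to 1 × 1 mm — was chosen so that a full
generate → normalise → extract → harmonise → evaluate sweep of one
normalisation variant completes in about a minute on one CPU, and the
bundled acceptance run (three variants plus ComBat, all protocols) in a few
minutes. The test suite exercises the same machinery on reduced cohorts
plus the full default cohort for the end-to-end properties. All randomness
flows from explicit seeds: the cohort seed fixes the generator, each
protocol seeds its own RNG, and `run_pipeline()` reruns byte-identically
under an identical configuration.

## Known limitations

* The phantom's two-class texture difference is stationary and isotropic;
  real HCM texture is regional and correlates with wall geometry.
* JSD small-sample bias (above) makes absolute %-below-τ values
  incomparable with large-cohort studies; only method-to-method contrasts
  are meaningful at this n.
* Histogram-matching quality depends on a single template subject by
  construction; the package mirrors this known fragility rather than
  repairing it.
* Whole-image normalisations are dominated by the background at typical
  cardiac field-of-view proportions, which is faithful to practice but
  means their fitted statistics mostly track air and chest wall.
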