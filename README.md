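# radharm

Multi-centre cardiac MRI radiomics: intensity normalisation, ComBat feature
harmonisation, and variability analysis.

## The problem

Radiomic features — quantitative descriptors of intensity and texture
computed inside a delineated region of interest — are highly sensitive to
scanner vendor, field inhomogeneity and acquisition protocol. In multi-centre
cardiac MR studies the raw grayscale has no physical unit (unlike CT
Hounsfield units), so the *same* tissue can span intensities of a few hundred
at one centre and above ten thousand at another. Any model trained on such
features risks learning the scanner, not the disease.

`radharm` implements, as a tested and reusable pipeline, the standard
machinery for quantifying and reducing that variability:

* **Image-level normalisation** applied at whole-image or per-ROI scope:
  rescaling to `[0, 1]` (`R`), z-normalisation (`N`), histogram matching to a
  template subject (`HM`), and Nyúl–Udupa piecewise linear histogram matching
  (`PLHM`), which maps each image's percentiles onto population-averaged
  standard-scale landmarks.
* **Radiomic feature extraction**: fixed-bin-width discretisation
  (`level(x) = floor((x - min)/W) + 1`; `W = 25` raw, `0.05` normalised) and
  the 88-feature texture panel per ROI — 18 first-order histogram features
  plus GLCM (24), GLRLM (16), GLSZM (16) and GLDM (14) texture-matrix
  features; shape features are excluded by design.
* **Feature-level harmonisation**: per-centre quantile Gaussianisation
  (K = 20) followed by parametric empirical-Bayes ComBat, aligned to a
  virtual reference: standardise `z = (y − α)/σ` with the pooled grand
  mean/SD, estimate per-centre location/scale effects `γ, δ²`, shrink them
  towards normal / inverse-gamma priors, and adjust
  `y* = σ(z − γ*)/δ* + α`.
* **Variability scoring**: sequential correlation filtering (drop features
  with `R² ≥ 0.9` against any earlier retained feature), base-2
  Jensen–Shannon divergence between per-centre feature distributions
  (bounded in `[0, 1]`), and the fraction of features with `JSD < 0.01`.
* **Twin random-forest evaluations**: *centre identification* (how much
  centre signal a feature set carries; 5-fold stratified CV, balanced
  accuracy — lower is better) and *cross-centre generalisation*
  (healthy-vs-HCM classification trained on a single centre, tested on all
  others; 5 seeds × 5 folds).

Because the underlying clinical images cannot ship with a package, `radharm`
includes a first-class synthetic cohort generator: a five-centre, two-class
(112 healthy / 106 hypertrophic cardiomyopathy) short-axis phantom cohort
whose per-centre intensity transforms and myocardial disease texture mimic
the statistical structure of real multi-centre data.

## Worked example

```r
library(radharm)

# a five-centre synthetic cohort (end-diastolic phase), resampled to 1x1 mm
studies <- generate_cohort(cohort_spec(seed = 1), phases = "ED")
studies <- lapply(studies, resample_inplane, target = c(1, 1))

# raw features vs ROI-rescaled features
ft_raw <- extract_cohort(studies, W = 25, resample_to = NULL)
norm   <- lapply(studies, \(s) apply_normalisation(s, "R", "roi"))
ft_rr  <- extract_cohort(norm, W = 0.05, resample_to = NULL)

# how much centre signal do myocardial texture features carry?
centre_id_protocol(ft_raw, order = "second", roi = "MYO", seed = 1)
#> <eval_report> task = centre_id (5 folds)
#>   CV balanced accuracy 1.000 +/- 0.000 (chance 0.20)

# ... and after quantile-Gaussianisation + ComBat?
centre_id_protocol(harmonise_features(ft_raw)$table,
                   order = "second", roi = "MYO", seed = 1)
#> <eval_report> task = centre_id (5 folds)
#>   CV balanced accuracy 0.260 +/- 0.098 (chance 0.20)

# does disease classification transfer to unseen centres?
generalisation_protocol(ft_raw, "SagradaFamilia", seed = 1)
#> <eval_report> task = generalisation (5 folds x 5 seeds, trained on SagradaFamilia)
#>   validation balanced accuracy 1.000 +/- 0.000
#>   test balanced accuracy 0.500 +/- 0.000 (chance 0.50)
generalisation_protocol(ft_rr, "SagradaFamilia", seed = 1)
#> <eval_report> task = generalisation (5 folds x 5 seeds, trained on SagradaFamilia)
#>   validation balanced accuracy 0.997 +/- 0.014
#>   test balanced accuracy 0.999 +/- 0.004 (chance 0.50)
```

Read: raw features identify the acquisition centre perfectly (balanced
accuracy 1.0 vs 0.2 chance) and a raw-feature disease model collapses to
chance on unseen centres (0.50) despite perfect within-centre validation —
the model learnt the scanner. ComBat removes the centre signal almost
entirely (0.26 ≈ chance), and ROI-level normalisation lets the disease model
generalise (0.999). `run_pipeline(run_config(...))` runs the full grid
(9 normalisation variants × with/without ComBat) and `render_report()`
produces the comparison tables.

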