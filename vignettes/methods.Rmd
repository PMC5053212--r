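---
title: "Dense-area mammographic features for interval versus screen-detected cancer: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense-area mammographic features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Interval breast cancer (IC) is diagnosed between two screening visits,
after a negative screen; screen-detected cancer (SC) is found at routine
screening. IC tends to be more aggressive, and the only established image
marker of IC risk in the normal breast has been percent mammographic
density (PD) — dense benign tissue can mask a growing tumor. This package
implements a case-case analysis that asks whether *features of the dense
area itself* — its texture, shape and spectral structure in the
pre-diagnostic mammogram of the contralateral (normal) breast —
differentiate future IC from SC beyond PD.

The pipeline has four stages, each a module of the package:

1. **Preprocessing** — artifact/nametag removal, intensity normalization,
   pectoral-muscle removal (`remove_artifacts`, `normalize_intensity`,
   `remove_pectoral`).
2. **Dense-area segmentation** — thresholding of breast pixels by Otsu's
   method (primary), the percentile (median) rule, and maximum-entropy
   (Kapur) thresholding (`dense_mask`).
3. **Feature extraction** — 32 named features of the dense area
   (`extract_features`), keeping the historical identifiers F1...F42 with
   their numbering gaps.
4. **Statistics** — Box-Cox standardization, a 3 x 32 battery of
   PD-adjusted logistic Wald tests, a global permutation test, forward AIC
   selection, a multivariate per-SD odds-ratio model, and stratified
   tumor-size regressions (`per_feature_tests`, `global_permutation_test`,
   `forward_select`, `fit_final_model`, `tumor_size_regression`).

Because the clinical mammograms and registry data behind such a study are
not publicly deposited, the package ships a first-class synthetic-data
module. All tests and the acceptance script run on synthetic material with
known ground truth.

## The synthetic phantom

`generate_breast_image()` builds a digitized-film-like MLO frame at 12-bit
dynamic range: a half-elliptical breast silhouette attached to the
chest-wall border, a pectoral triangle in the upper chest-wall corner, an
off-breast rectangular nametag, and a dense region. The intensity layout
(background 0, fat 0.35, dense 0.70, pectoral 0.92, nametag 0.98, as
fractions of the intensity range; `sim_intensity_levels`) was chosen once
so that the tissue classes are ordered as on film and Otsu thresholding
inside the breast separates fat from dense tissue.

The dense region is the level set of an anisotropic Gaussian — a rotated
ellipse — whose pixel count matches the requested `dense_fraction` of the
breast (minus pectoral) area and whose axis ratio encodes the requested
`dense_eccentricity`. Fatty-streak interspersion is modelled by carving
sinusoidal low-intensity channels through the dense region with Gaussian
cross-profile; the `streak_intensity` knob is the carve depth as a
multiple of the dense-fat contrast. The streak count scales with the
dense-region size (up to 3) so that streak walls remain a small,
outlier-like fraction of dense pixels at any image size; this keeps the
amplitude response of the gradient-skewness feature (F40) monotone, which
is the property the knob exists to drive. Additive Gaussian noise
(default SD 40 intensity units, about 1% of the 12-bit range) emulates
film-digitizer noise.

Each image draws from a private RNG stream derived from its seed, so runs
are bit-reproducible and parallel generation cannot interleave streams.

What the phantom does *not* emulate: radiographic physics, 3-D anatomy,
scatter, compression folds, or digitizer artifacts beyond nametags.
Passing tests on this material demonstrates the internal correctness and
statistical calibration of the pipeline, not clinical validity on film.

## The synthetic cohort

`generate_cohort()` draws, per woman: PD lognormal (median about 19%,
right-skewed), BMI normal (25.4, SD 4), age at diagnosis normal (60.4,
SD 8), HRT use Bernoulli(0.18), and two latent standardized image traits
f40 and f21. IC status is Bernoulli with logistic probability in the
standardized covariates; the default effects are per-SD odds ratios 1.23
(PD), 0.84 (BMI), 0.98 (age), 1.57 (HRT use) and — the effects under
study — 1.32 for the gradient-skewness trait and 1.20 for the
eccentricity trait. Square-root tumor size is a stratum-specific linear
predictor plus unit-SD noise, squared, floored at 1 mm so the sqrt
transform stays defined; the default feature effects on sqrt size are
0.20 per SD (f40, SC stratum) and -0.18 per SD (f21, IC stratum).
Field-wise missingness defaults mirror a realistic registry table (3-8%
for questionnaire fields, much higher for tumor grade). These defaults are
conventions of the generator, chosen once; the source cohort's images are
not being claimed to follow these distributions.

## Preprocessing choices

* Foreground threshold for artifact removal: 2% of the intensity range,
  robust for near-zero film background; the breast is the largest
  8-connected foreground component.
* Normalization maps the 1st/99th breast-pixel percentiles to 0/1
  (clipped). Percentiles rather than min-max resist stray specks; the map
  is monotone so all rank-based downstream quantities are unaffected.
* Pectoral removal: candidate bright pixels in the upper chest-wall
  quadrant, the component attached to the chest wall, and a least-squares
  straight-line fit to its per-row outer boundary; everything on the
  corner side of the line (plus a 1.5 px outward margin, which absorbs
  noise-displaced boundary pixels) is removed. A straight-line boundary is
  a simplification chosen for testability against the phantom's triangle;
  if no credible corner region exists the mask is returned unchanged with
  a warning.
* Fixed order: artifacts, then normalization, then pectoral removal; every
  output mask is a subset of its input.

## Segmentation choices

Thresholds operate on a 256-bin histogram of normalized breast-pixel
intensities (the 12-bit native resolution collapsed 16:1, which
stabilizes entropy estimates). "Dense" means *strictly above* the
threshold, which makes the percentile method's dense fraction provably at
most 50%. The histogram is taken over breast-mask pixels only, since the
dense area is defined within the breast; this is a documented choice, not
a claim about the original implementation. Both optimizing thresholds
(Otsu: minimal weighted within-class variance; Kapur: maximal summed
class entropies with 0 log 0 := 0) break ties toward the lowest
threshold and are verified bin-exactly against exhaustive search.

`percent_density_proxy()` — the dense-pixel fraction of the breast area —
stands in for PD on synthetic runs only; the study's PD measurement
algorithm is out of scope and PD enters the statistics as a covariate.

## Feature conventions

Texture/transform features operate on the `dense_patch`: the tight
bounding-box crop with non-dense pixels zeroed. Key conventions, fixed in
one place and validated against independent naive oracles rather than
claimed to be bitwise-faithful to any original code:

* Moments are population m-statistics (no small-sample correction);
  entropies are in bits with 256 histogram bins.
* F40 (gradient skewness) samples central-difference gradient magnitudes
  at *interior* dense pixels (all four neighbors dense). Including
  silhouette-boundary pixels would let the artificial step at the crop
  edge dominate the third moment and would decouple the statistic from
  the fatty-streak structure it is meant to measure.
* Shape features pool all 8-connected components; holes are 4-connected
  enclosed background regions; the Euler number is components minus
  holes; solidity uses the convex hull of pixel squares (so it is at
  most 1); eccentricity comes from the second central moments of the
  pooled dense pixel set.
* DFT maxima exclude the DC bin for F11/F17 (otherwise the maximum is
  trivially the mean) but keep it for F3/F14, whose inputs are filtered
  images with informative means.
* The wavelet approximation (F2) uses a periodic Daubechies-4 transform at
  3 levels, zero-padded to a multiple of 8.
* The log-Gabor bank is 2 scales (1/6 and 1/12 cycles/pixel, sigma/f =
  0.65) x 4 orientations (angular sigma 0.6 rad), single-sided so the
  response is complex; responses are averaged over the bank before the
  entropy is taken.
* Co-occurrence matrices quantize dense pixels to 32 levels, count only
  pairs inside the mask, and are symmetrized and normalized.
* Undefined values (zero variance, no valid pixel pairs, degenerate
  patches) are stored as 0 with a flag; the statistics stage drops
  flagged values per feature.

## Statistical choices

* Box-Cox: shift `max(0, 1 - min(x))`, lambda by profile maximum
  likelihood over [-3, 3], then center/scale to SD 1. The fitted spec is
  stored so transforms replay on new data.
* The per-feature battery fits IC/SC ~ feature + PD per (method, feature)
  on that model's complete cases; two-sided Wald p-values. Non-converged
  or separated fits are flagged and excluded from the global statistic
  (their count is reported) rather than imputed.
* The global statistic is the count of the 96 tests with p below 0.05;
  its null distribution comes from permuting IC/SC labels over women,
  keeping each woman's covariates and features attached — this respects
  the correlation between features, unlike a Bonferroni-style count test.
  The empirical p uses the strict "greater than" fraction; an add-one
  variant is available behind a flag. Features are transformed once
  before permuting: under the null the labels are exchangeable given the
  fixed features, and re-estimating lambda per permutation would multiply
  the cost by the permutation count for no change in exchangeability.
  The permutation loop uses a compiled batched IRLS (the 96 models share
  their intercept and PD columns), verified against `stats::glm`.
* Forward selection is greedy AIC on top of the base model (PD, age, BMI,
  HRT), complete cases fixed at the start so AICs are comparable; ties
  break by feature order. AIC matches the default behavior of standard
  stepwise selection in R.
* The final model reports per-SD odds ratios: continuous covariates are
  standardized, HRT enters as an indicator; an optional standardized
  time-from-mammogram-to-diagnosis covariate supports the sensitivity
  analysis.
* Tumor-size models regress sqrt(size in mm) on the standardized feature
  within a detection-mode stratum (size is left-skewed; the sqrt is the
  variance-stabilizing choice, and the generator floors size at 1 mm).
* The characteristics summary uses Welch t-tests for continuous variables
  (the unequal-variance default is the safe reading of "two-sided t
  test") and Pearson chi-square without continuity correction for
  categorical ones; percentages are of non-missing values within group,
  rounded to integers.
* Missing data: complete cases per model throughout, which is why
  different models report different n.
* No per-test multiplicity correction is applied; the family is
  controlled by the global permutation test.

## Problem sizes

The test-suite simulations use sizes chosen to make the statistical
properties sharp at desk scale: threshold oracles on 100 random 256-bin
histograms; feature oracles on 20 random patches between 16 and 64 pixels
per side; permutation calibration on 100 null cohorts of n = 500 with 200
permutations and power on 50 cohorts of n = 1500 with 5 signal features;
effect-size recovery on 100 cohorts of n = 1400; end-to-end sign recovery
on 100 imaging cohorts of 600 images at 96 x 76 pixels. The demonstration
workflow under `analysis/` runs 60 images at 256 x 200.

## Known limitations

* The preprocessing stand-ins (straight-line pectoral boundary, 2%
  foreground rule) are validated against the phantom only; film
  digitizations with curved pectoral boundaries would need a richer
  boundary model.
* Feature definitions are internally consistent and oracle-checked, but
  several one-line feature descriptions underdetermine the original
  operators (which matrix the SVD acts on, Gabor pooling, window sizes);
  numeric identity with any other implementation is not claimed.
* The amplitude response of F40 to streak carving is monotone over the
  simulated range but need not be monotone for arbitrarily shaped
  streaks; the e2e simulation maps its latent trait into the rising part
  of the response.
* The percentile method's dense area is capped at half the breast by
  construction; comparisons of PD proxies across methods should keep that
  in mind.
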