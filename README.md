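# mammodense

Dense-area mammographic image features for differentiating interval from
screen-detected breast cancer.

## The problem

Interval cancers (IC) surface clinically between two screening visits,
after a negative screen; screen-detected cancers (SC) are caught at
routine screening. IC is the costlier outcome — typically larger, more
often node-positive — and the only established image marker of IC risk in
the *normal* breast has been percent mammographic density (PD), through
tumor masking. This package implements a case-case analysis pipeline for
a sharper question: do properties of the dense area itself — its texture,
shape and spectral structure in the pre-diagnostic mediolateral-oblique
mammogram of the contralateral breast — separate future IC from SC
*beyond* PD?

It is aimed at breast-imaging epidemiologists and image-analysis
methodologists who want a tested, fully synthetic-reproducible
implementation of that analysis: image preprocessing, three dense-area
thresholding rules, 32 dense-area features, and the complete inference
stage.

## The method

For each woman, the mammogram is preprocessed (nametag/artifact removal,
1st/99th-percentile intensity normalization, pectoral-muscle removal) and
the dense area is segmented as the breast pixels strictly above a
threshold chosen by one of:

* **Otsu's method** (primary): minimize the weighted within-class
  intensity variance;
* **percentile rule**: threshold at the median breast intensity;
* **maximum entropy (Kapur)**: maximize the summed Shannon entropies of
  the two intensity classes.

From the dense area, 32 features (identifiers F1–F42 with historical
gaps) are computed: histogram statistics, gradient skewness, region shape
(blob count, solidity, eccentricity, Euler number, holes, perimeter),
projection kurtosis, DCT/DFT/wavelet and filtered-spectrum maxima,
log-Gabor response entropies, a local-entropy mean, co-occurrence entropy
and energies, and singular-value statistics.

Inference, with IC-vs-SC as the outcome: each feature is Box-Cox
transformed and standardized, then tested per method in

&nbsp;&nbsp;&nbsp;&nbsp;logit P(IC) = β₀ + β₁·feature + β₂·PD

giving a 3 × 32 grid of Wald p-values. A **global permutation test**
counts the tests with p < 0.05 and permutes IC/SC labels over women
(features stay attached to the woman, preserving their correlation) to
get an empirical global p. Features are then forward-selected by AIC into
a multivariate model with PD, age, BMI and HRT, reported as per-SD odds
ratios with 95% CIs; stratified linear models of √(tumor size) per SD of
each selected feature complete the analysis.

Everything runs on a first-class synthetic module: a mammogram phantom
(breast silhouette, pectoral triangle, nametag, controllable dense-area
fraction/eccentricity/fatty-streak interspersion, with ground-truth
masks) and a cohort generator with known effect sizes.

## Worked example

```r
library(mammodense)

sim <- generate_breast_image(image_sim_params(dense_fraction = 0.25, seed = 4))
pre <- preprocess_image(sim$image)
dm  <- dense_mask(pre$image, pre$mask, "otsu")
round(percent_density_proxy(dm, pre$mask), 1)
#> [1] 25.1

fv <- extract_features(pre$image, dm)
round(fv[c("F40", "F21", "F19", "F20")], 3)
#>   F40   F21   F19   F20 
#> 1.837 0.500 1.000 0.983

ch  <- generate_cohort(cohort_sim_params(n = 1400, seed = 3))
res <- fit_final_model(ch, ch[, c("id", "f40", "f21")],
                       features = c("f40", "f21"))
res[res$term %in% c("f40", "f21"), c("term", "effect", "ci_lower", "ci_upper")]
#>   term   effect ci_lower ci_upper
#> 5  f40 1.442727 1.269890 1.639088
#> 6  f21 1.311316 1.156452 1.486918
```

The PD proxy recovers the simulated dense fraction (25.1% for a target of
25%). The feature vector shows a moderately streaked (F40 = 1.84),
mid-eccentricity (F21 = 0.50) single-blob dense area of high solidity
(F20 = 0.98). The cohort fit
recovers per-SD odds ratios whose confidence intervals cover the
generating effects (1.32 for the gradient-skewness trait, 1.20 for
eccentricity).

A complete demonstration workflow — simulate 60 mammograms and a cohort,
preprocess/segment, extract the 3 × 32 feature table, and run the whole
statistical stage — lives in `analysis/01_simulate.R` through
`analysis/04_analyze.R`, writing its tables under `results/`.

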