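---
title: "Automated mammographic density: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated mammographic density: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Mammographic density — the proportion of radiologically dense fibroglandular
tissue on a mammogram — is one of the strongest known risk factors for breast
cancer. The reference way of quantifying it, an interactive thresholding read
(percent density, PD = 100 × dense area / total breast area), takes a trained
reader minutes per film. This package implements a fully automated
alternative for digitized film mammograms: a fixed battery of classical
global-thresholding segmentations is measured into a large per-image feature
vector, reduced by principal components, and a lasso model is trained to
mimic a reference PD read; penalized logistic models on the same components
provide risk scores that can carry information beyond PD. This vignette
records the model assumptions, the tunable parameters, and the design
decisions that were genuinely open.

## Preprocessing

Identification tags are removed first (`crop_tag()`). In automatic mode a
tag is a bright 8-connected component that (a) touches both borders adjacent
to one image corner, (b) occupies less than 5% of the image, and (c) has
mean intensity above the global minimum-error threshold. Detected tag pixels
are replaced by the image minimum — the film-background level — so they can
never enter a downstream mask. The three conditions are this package's
operationalization of "automatic tag removal"; real archives vary in tag
placement, and a conservative rule plus the explicit-rectangle fallback was
preferred over a learned detector.

The breast region (`background_mask()`) comes from grayscale erosion
followed by Gaussian smoothing, a Kittler–Illingworth minimum-error
threshold on the 256-level histogram of the smoothed image, and retention of
the largest connected foreground component. Erosion radius (5 px) and blur
sigma (4 px) are stated at a nominal 1000-px image height and scale linearly
with height; the source workflow does not state them, so they are exposed as
arguments. The minimum-error threshold is computed by exhaustive scan of the
two-Gaussian misclassification cost, with class variances floored at 1/12
(the quantization variance) so single-level classes stay finite; ties break
toward the lower level, the convention used by every method in the package.

## The thresholding suite

`auto_threshold()` implements the fifteen classical global methods of the
ImageJ auto-threshold roster — IsoData, Huang, Intermodes, Li, MaxEntropy,
Mean, MinError, Minimum, Moments, Otsu, Percentile, RenyiEntropy, Shanbhag,
Triangle, Yen — each from its published objective, on 256-level histograms
(deeper images are linearly rescaled; the threshold maps back to the top
intensity of its bin, and "dense" means strictly greater than the cut).
Two details worth stating exactly:

* RenyiEntropy is the three-order combination (orders 1/2, 1 and 2) with
  the closeness-based weights of the published method, not a single-order
  scan.
* Triangle's geometric argmax is clamped into the range where both classes
  keep mass; on degenerate spike histograms the unclamped geometry can
  land outside the support.

Every method is deterministic, scale-invariant in the counts, and tested
against an independent naive reimplementation of its objective on 200
seeded bimodal histograms.

## Feature extraction

Per image, `extract_features()` fills a fixed 1,008-slot layout
(`feature_layout()`): 10 whole-breast intensity statistics, 8 statistics of
a Sobel edge pass, and per thresholding method 66 slots — 16 statistics for
the single "5+ px" size class of variant A (thresholding the preprocessed
image), 16 × 3 for the 1–100 / 101–1000 / 1001+ px classes of variant B
(rolling-ball background subtraction, radius 50 px; 3×3 median de-noising;
distance-transform watershed object splitting), and two binary-thinning
slots (skeleton pixel count, skeleton/dense-area ratio). The per-class
statistics are Count, TotalArea, AverageSize, AreaFraction, integrated
density, and unweighted means over member objects of mean/modal/median
gray, skewness, excess kurtosis, circularity, solidity, perimeter, and the
best-fit-ellipse major, minor and angle. The published workflow reports the
same overall budget of 1,008 measurements but never its decomposition; the
layout here is explicit, versioned, and carries a content hash — the
contract is the registry, not the count.

Numerical conventions that matter downstream:

* Perimeter is the Moore-traced 8-connected boundary chain with
  Vossepoel–Smeulders corrected weights (0.980 axial, 1.406 diagonal,
  −0.091 per corner). The raw √2-weighted chain overestimates smooth
  boundaries by ~5%, which would bias circularity of a true circle to
  ~0.91; with the correction disc circularity converges to 1.0 from above
  (1.012 at radius 50). Squares still exceed 1 slightly (≈1.03), which is
  expected for digitized shapes; a clamp flag exists and defaults off.
* Kurtosis is excess kurtosis (fourth standardized moment minus 3).
* Modal gray ties break toward the lowest level.
* Solidity uses the convex hull of boundary-pixel corners, clamped at 1.
* Empty size classes keep definitional zeros (Count, TotalArea,
  AreaFraction) and NaN for everything that averages over members; a pass
  that fails outright (e.g. a histogram the mode-seeking methods cannot
  make bimodal) writes NaN into all its slots and never aborts the vector.
* Both the edge pass and the thinning pass are measured whole-image (the
  alternative per-object reading of the source workflow is not
  implemented); the thinning pass skeletonizes the variant-A dense mask.

## Feature matrix, PCA

`filter_missing()` keeps columns with fewer than `max_nan` undefined
entries (default 200, the working rule at a ~3,000-image cohort; a
fraction-of-rows variant is provided for other cohort sizes) and then
converts the surviving NaNs to zero. PCA (`fit_pca()`) is on the covariance
of the centered, unscaled columns — the variables enter raw, matching the
described workflow; a scale flag exists. The basis keeps the smallest
number of components reaching 90% cumulative variance by default, uses a
deterministic sign convention (largest-magnitude loading positive), and is
fitted on training rows only; projection always centers by the training
means.

## Lasso models

The penalized fits are authored coordinate descent on the full-likelihood
objective (−logLik + λ‖β‖₁; RSS/2 for the gaussian family), IRLS outside
coordinate descent for the binomial family, with intercept and any declared
covariates unpenalized and a 1e-7 tolerance on coefficient updates.
`cv_lambda()` repeats k-fold cross-validation (10 folds by default;
stratified by case status for the binomial family), finds each repeat's
optimal λ by golden-section search on the log scale of the out-of-fold
likelihood, and returns the arithmetic mean over repeats — the "mean
lambda" convention; whether that mean was arithmetic or geometric in the
source workflow is unstated, and arithmetic was chosen. The λ search upper
bound comes from the KKT condition at the all-zero penalized model, with
residuals taken from the fit of the unpenalized covariates alone. This
detail is load-bearing: with the naive null-residual bound, score-2 fits
(PD forced in unpenalized) can pick up a large collinearity artifact in
which the unpenalized PD coefficient overshoots and a density-correlated
component compensates with the opposite sign.

One deliberate deviation from the described workflow: inside
`train_pd_model()` and `train_score_model()` the covariates are
standardized to unit variance for the penalized fit by default (the fitted
coefficients are reported back on the original scale, and a flag restores
the raw behaviour). Covariance-PCA scores of raw image features span many
orders of magnitude — integrated densities are ~10⁷, area fractions ~10¹ —
so a single λ cannot penalize all components at once: at any λ that
touches the small components, the large ones are effectively unpenalized,
which in the score-2 layout produces a collinearity artifact (the
unpenalized PD coefficient overshoots and the density-correlated top
component compensates with the opposite sign).

The PD mimic (`train_pd_model()`) regresses √PD on the components (the
square-root transform makes PD approximately normal); predictions floor the
linear predictor at 0, square it, and cap at 100. The three risk scores
(`train_score_model()`) are penalized logistic fits of case status on the
components alone (score 1), with PD added unpenalized (score 2) or
penalized (score 3); a score's value is always the sum of its nonzero PC
coefficients times the PC values — the PD coefficient never enters the
score. PD appears in these models on the √ scale, consistent with the PD
modeling; the source workflow does not state the scale. Known behavior of
the CV-optimal lasso, confirmed against an independent CV implementation:
it recovers true supports with full recall but overselects small spurious
coefficients; support-precision claims beyond that are not achievable under
this selection rule.

## Evaluation battery

`evaluation_report()` bundles Pearson r with a Fisher-z interval,
Bland–Altman agreement (mean difference, ±1.96·SD limits, and the
difference-on-mean regression), categorical odds-ratio profiles by
unconditional logistic regression (default breaks 0/5/10/25/100 — a low
reference under 5% with the upper categories merged; the 0/10/25/50/75/100
display preset is also available), ROC AUCs with DeLong variance, the
DeLong two-sided test for paired AUCs (½ tie convention), and a
deviance/LRT/AIC table over the standard eight model rows. In that table
`P1` tests each model against the intercept-only null and `P2` tests a
PD + score model against its PD-only reference — the interpretation
adopted for the ambiguous two-column layout; AIC is deviance + 2 ×
parameter count.

## The phantom generator

`generate_phantom()` states a 256 × 256, 12-bit world: film background at
intensity 150; a half-elliptical breast (semi-axes 0.70 × width,
0.42 × height, anchored on the left edge) at base level 1000; dense tissue
as the top quantile of a Gaussian random field (smoothing sigma 6 px)
inside the breast, hit exactly at the requested percent density and boosted
by +900; multiplicative vignetting (strength 0.25) toward the breast edge;
an optional 3500-level corner tag; a light 0.8-px blur; and additive
Gaussian noise (SD 15). Truth masks are recorded before noise, so true PD
is an exact pixel-count ratio. `generate_cohort()` draws per-subject √PD
from a truncated normal (mean 3.32 = √11, SD 1.5, support [0.5, 9]) and
shifts cases by +0.8 on the √PD scale: these numbers reproduce the
case/control median split of ~16.9% vs ~11.0% PD and an upper PD range of
~80% reported for the population the method was developed on.

What the phantoms do *not* emulate: pectoral muscle, scanner artifacts
other than one corner tag, spatially correlated film grain, and any
texture-risk signal beyond density itself. A green end-to-end test
therefore establishes that the pipeline measures density correctly and
propagates a density-mediated risk difference — not that it would rank
real parenchymal textures. In particular, because the phantom cohort
carries no extra-PD risk information and its reference PD is exact, the
score-2/score-3 contrast on phantoms reflects the collinearity mechanics of
the two penalty layouts rather than genuine extra information; the
dedicated unit test constructs a world with weak density-reading components
and a latent texture axis to exercise the mechanism the scores were
designed for.

## Runtime and scaling notes

Feature extraction runs at roughly one second per 256 × 256 phantom on one
CPU, dominated by the 15 × 2 segmentation passes. The test suite and the
acceptance script keep the stated cohort sizes (100 phantoms for parameter
recovery, 200 + 200 for the risk direction) but reduce the number of
cross-validation repeats from the default 100 to 2; lambda selection is the
only thing that depends on repeats, and the mean over 2 seeded repeats is a
noisier but unbiased version of the same rule.

## Known limitations

* Only PNG and PGM rasters are read (no TIFF decoder is available in the
  dependency set); 12-bit data travels in 16-bit PNG or native PGM.
* Pectoral-muscle removal and cranio-caudal views are out of scope.
* The auto tag detector assumes corner-adjacent bright tags.
* Watershed over-segmentation on noisy masks is accepted (labels ≥
  components is the only guarantee), as the size-class statistics are
  aggregates.
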