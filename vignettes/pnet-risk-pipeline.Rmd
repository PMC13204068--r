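---
title: "Methods: preoperative PNET risk stratification from CT radiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preoperative PNET risk stratification from CT radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnetrad)
```

## The problem

Pancreatic neuroendocrine tumors (PNETs) range from indolent to highly
aggressive, and the main prognostic anchor — histologic grade by Ki-67 and
mitotic rate — is only reliable after resection. Fine-needle biopsy
frequently under-samples the tumor, so a preoperative, imaging-based risk
estimate is clinically valuable: it can inform the extent of lymph-node
dissection, the case for neoadjuvant therapy, and surveillance intensity.

`pnetrad` implements a complete, testable pipeline for this problem:
radiomic feature extraction from portal-venous-phase CT, cross-center
harmonization, spatial delta-radiomics against a per-patient internal
control, a small prespecified panel of hybrid clinico-radiomic signatures,
univariable survival analysis with resampling inference, and a nested
cross-validated classification study with TRIPOD-style calibration and
leave-one-center-out (LOCO) validation. Because surgical PNET cohorts are
small and rarely public, the package ships a synthetic-data generator that
emulates a two-center cohort of 44 patients, so every stage runs and is
tested end to end without patient data.

## The measurement model behind delta-radiomics

For any radiomic feature $f$ measured on the lesion ROI,

$$ f_{\text{lesion}} \approx f_{\text{biology}} + f_{\text{patient}} +
f_{\text{scanner}} + \varepsilon, $$

where the patient term (body habitus, contrast timing) and the scanner term
(device, protocol, center) are shared with *any other ROI from the same
acquisition*. The contralateral, non-tumor-bearing pancreas inherits
$f_{\text{patient}} + f_{\text{scanner}}$ but contributes no tumor signal,
so the spatial delta

$$ \Delta X = X^{\text{lesion}} - X^{\text{pancreas}} $$

cancels the shared nuisance components — the same logic as reference-region
normalization in PET or $\Delta\Delta C_t$ in qPCR. This is complementary
to ComBat: ComBat removes the *between-center* location/scale batch effect,
the delta removes the *within-patient* common-mode signal that no
population-level model can see. Shape features are excluded from the delta
pool because they are dominated by the trivial lesion-versus-pancreas size
difference.

The synthetic generator (`nuisance_model()`, `generate_feature_table()`)
implements exactly this decomposition with controllable variance
components, which is what makes the cancellation property testable: with
`sigma_patient = sigma_scanner = 0` and no noise, the delta *is* the
biology term; with shared nuisance switched on, the correlation between
the delta-feature and the clinical aggressiveness score exceeds that of
the raw lesion feature (asserted on averages over 50 generator seeds).

## Feature extraction

`extract_features()` follows the common IBSI-style chain:

* **Resampling** to isotropic 1 mm voxels. The image uses a separable
  cubic B-spline with its interpolating prefilter (an identity resampling
  reproduces the input exactly); the mask uses linear interpolation with a
  0.5 threshold. Both interpolators are implemented in the package since
  the installed R stack has no 3D resampler.
* **Resegmentation** to $[-150, 240]$ HU, removing in-mask voxels outside
  the soft-tissue window.
* **Discretization** with a fixed 25 HU bin width anchored at the in-ROI
  minimum (`bin_anchor = "fixed"` switches to the window edge).
* **Feature classes**: first-order, shape, GLCM, GLRLM, GLSZM, GLDM and
  NGTDM, about 60 features. Texture matrices are 3D with 26-connected
  neighborhoods at distance 1; GLCM/GLRLM use the 13 unique directions and
  features are averaged over directions. Full parity with any particular
  extraction tool's 110-feature inventory is *not* promised; the panel
  below only requires the primitives named in it, and those are checked
  against brute-force oracles on small arrays.

Numerical conventions worth stating: NGTDM Busyness returns 0 when the ROI
has a single gray level (zero denominator); Coarseness caps at $10^6$;
volume is voxel count times voxel volume; surface area comes from a
marching-tetrahedra triangulation of the 0.5-isosurface of the mask
indicator, lightly smoothed (Gaussian, 0.6 voxel) so that a digitized
10 mm ball scores sphericity $\approx 0.96$ rather than the inflated value
a raw staircase surface gives. The voxel-face surface convention is
exposed for closed-form checks (a single 1 mm voxel then has sphericity
$(36\pi)^{1/3}/6 \approx 0.806$). Axis lengths use the
$4\sqrt{\lambda}$ convention on the population covariance of voxel-center
coordinates; for a solid ellipsoid with semi-axis $a$ this gives
$4a/\sqrt 5 \approx 1.79a$, which the tests assert analytically.

## Harmonization

`combat_fit()` / `combat_transform()` implement parametric empirical-Bayes
ComBat with center as the batch: features are standardized by grand mean
and pooled variance, per-batch location and scale get normal and
inverse-gamma priors (hyperparameters by method of moments), and the
posterior estimates are found by iterated conditional modes (tolerance
$10^{-6}$, max 100 iterations). No biological covariates enter the design;
instead `balance_check()` verifies covariate balance across centers first
(Mann–Whitney U for continuous, Fisher exact for binary covariates), which
is the appropriate order of operations when centers are biologically
comparable. Lesion and pancreas rows are pooled in one fit so both ROIs of
a patient share center parameters — a prerequisite for the delta to be
taken on a common scale. The fit/transform split (rather than a single
adjust call) exists so LOCO validation can apply a training-center model to
held-out data without refitting, and the model serializes to JSON for
audit. Tests cross-check the transform against the reference Bioconductor
implementation on a fixture.

Two practical notes. Zero-variance features are passed through unadjusted
with a warning. And EB refitting is only idempotent up to sampling noise:
refitting on harmonized output moves values by the $O(n^{-1/2})$ residual
of the first fit, which the tests bound at 5% of the first pass rather
than pretending machine-precision idempotence.

## The signature panel

Ten prespecified products of one radiomic primitive and one preoperative
clinical variable (Ki-67 as a fraction of 1; grade coded 1/2/3; functional
status 0/1):

| ID | Formula |
|----|---------|
| A1 | Entropy × Ki-67 |
| A2 | (Surface/Volume) × (1 − Sphericity) |
| A3 | (1 − Sphericity) × Functional × Grade |
| A4 | log(Energy + 1) × Grade × (1 + N metastatic organs) |
| A5 | A1 × A2 |
| A6 | NGTDM Busyness × Ki-67 |
| A7 | Median HU × Grade |
| B1 | ΔEntropy × Ki-67 |
| B2 | ΔBusyness × Ki-67 |
| B3 | ΔMedianHU × Grade |

Family A uses harmonized lesion values; Family B replaces the radiomic
multiplicand with its delta-feature. Design choices where the panel
definition left room: the logarithm in A4 is natural; A4's Energy is the
harmonized lesion value; functional status enters literally as 0/1, which
zeroes A3 for nonfunctional patients (flagged, but kept as defined);
missing multiplicands propagate to a missing signature rather than zero,
so each signature carries its own complete-case `n` downstream. Shape
collinearity is summarized separately by PCA of the correlation matrix of
the lesion shape features, retaining three components with a
deterministic sign convention (dominant loading positive).

## Survival analysis

Each signature is z-standardized within its complete-case subset (sample
SD, $n-1$) and entered into univariable Cox regression with Efron tie
handling; hazard ratios are per 1-SD. Confidence intervals are
profile-likelihood: each bound solves
$2\{\ell(\hat\beta) - \ell(\beta)\} = \chi^2_1(0.95)$ by bisection, which
behaves far better than Wald intervals in small-event settings (about 16
events here). Wald p-values are reported (LRT available). Monotone
likelihoods are flagged with an infinite bound rather than crashing.
Events-per-variable ≈ 1 rules out multivariable Cox, deliberately.

Discrimination per signature is Harrell's c, with a 2000-resample
percentile bootstrap CI over patients and a 1000-permutation p-value on
the direction-free scale $|c| = \max(c, 1-c)$, permuting the signature
against fixed (time, event) pairs. Median-split Kaplan–Meier curves use
Greenwood variance with log(−log) 95% bands (respecting $[0,1]$), ties at
the median going to the low group, and a two-group log-rank test; a
hand-computed product-limit table pins the estimator in the tests.

## Prediction study

Two binary targets — progression and higher grade (G2/G3 at biopsy) — and
three predictor blocks each: **M0**, five preoperative clinical variables
(age, sex, imaging tumor size, biopsy grade, biopsy Ki-67); **MA** = M0 +
Family A; **MB** = M0 + Family B. For the higher-grade target, biopsy
grade is removed from M0 (functional status substitutes to keep five
variables) and the grade-containing signatures A3, A4, A7 and B3 are
excluded — the target would otherwise leak into its own predictors.

`nested_cv()` runs outer 5-fold stratified CV for out-of-fold (OOF)
predictions and an inner 5-fold loop that selects the top-$k$ features
(ANOVA-F filter, $k \in \{2,3,5\}$). Median imputation, z-scaling and
selection are all fit on training folds only; the permuted-label
acceptance test verifies the whole pipeline leaks nothing (mean OOF AUC in
[0.45, 0.55] over 50 permutations for every block and target). Three
classifiers are supported — logistic regression, random forest (500
trees), gradient boosting (depth 2, learning rate 0.1, 100 rounds) — with
only $k$ tuned, all other hyperparameters fixed at conventional defaults.
Reported per block: pooled OOF AUC with a 2000-resample bootstrap CI,
Brier score, and the TRIPOD calibration intercept and slope from the
logistic regression of the outcome on logit of the OOF probability
(probabilities clipped at $10^{-6}$; the slope-fixed-at-1 intercept is
also reported). `loco_cv()` trains the same pipeline on one center and
predicts the other, both directions, pooling predictions into one AUC with
a 1000-resample CI — the strongest internal proxy for external validation
a two-center cohort permits. Pooled LOCO AUC is interpretable only when
outcome prevalence is comparable across centers; with a strong prevalence
imbalance the pooled estimate can fall below either within-center value.

## Descriptive statistics

`lesion_vs_pancreas()` computes the volcano statistics: per feature an
unpaired two-sided Mann–Whitney U test (as printed in the source analysis;
a paired signed-rank variant sits behind `paired = TRUE`), Cohen's d with
pooled SD and the pancreas-minus-lesion sign convention (lesions scoring
higher get negative d), and BH-FDR at q < 0.05.
`radiomic_clinical_correlations()` maps Spearman correlations (average
ranks for ties) of every feature against the clinical variables with
BH-FDR over the full grid; degenerate cells are flagged, not errors.

## What the synthetic generator does and does not emulate

`cohort_profile()` defaults encode the two-center study conditions: 44
patients, grade mix 24/15/4 with one missing biopsy grade, cohort Ki-67
median pinned at 4.0% (log-normal per grade, monotone rescale), five
missing Ki-67 values, 6 functional tumors, 22 patients with at least one
metastatic organ, progression 16/43, mortality 8/43, follow-up median 38
(IQR 14–59) months. Categorical marginals are hit exactly by sampling
without replacement; events fall preferentially on aggressive disease
(weighted exact-count sampling, log-odds weight 1.2 on the standardized
grade + log Ki-67 score), which reproduces the qualitative study behavior
— several Cox-significant signatures and useful prediction AUCs — without
targeting any printed effect size. Values the tables do not print (center
split 22/22, the 14/6/2 split of 1–3 metastatic organs, per-grade Ki-67
log-scale parameters, the lesion-versus-pancreas mean shifts) were chosen
once as field-realistic and are documented in `default_config()`.

The optional 3D phantoms are ellipsoidal ROIs with Gaussian-random-field
texture of stated correlation length, plus a whole-volume scanner offset
and voxel noise. They exercise the geometry and texture code paths
(including the common-mode cancellation of the scanner offset in the
delta) but are not anatomically realistic: no duct, no vasculature, no
contrast-phase or respiratory structure. Passing tests on synthetic data
therefore demonstrate the *statistical machinery* — exact marginals,
nuisance cancellation, calibration and leakage control — not clinical
validity on real CT, which requires the real-data mode
(`read_phantom()`-style NIfTI volumes plus a clinical CSV) and an actual
cohort.

Outcome times follow an exponential proportional-hazards model in
`attach_outcomes()` (chosen over Weibull for analytic tractability of the
closed-form checks); follow-up and censoring in the cohort generator are
log-normal, matched to the printed quantiles.

## Numerical and design decisions, collected

* Sample-SD (n−1) z-standardization; HRs per 1-SD depend on it.
* Profile-likelihood bisection tolerance $10^{-6}$ on $\beta$; bound
  search caps at $|\beta| > 50$, reporting an infinite bound (monotone
  likelihood flag).
* ComBat iteration tolerance $10^{-6}$, max 100 iterations; single-batch
  input degrades to the identity with a warning.
* Correlation clustering threshold $|\rho| \ge 0.80$; cluster
  representative is the medoid, ties broken by feature name; LRT screen at
  BH-FDR < 0.10; stability selection 100 bootstraps at ≥ 60%. Separation
  in the screening logistic model falls back to a small-ridge IRLS fit
  (λ = $10^{-3}$) with a warning.
* Degenerate inputs: empty ROI after resegmentation errors with the ROI
  name; constant predictions error in calibration; a center missing an
  outcome class makes LOCO return NaN with a warning; degenerate bootstrap
  resamples (single class) are redrawn and counted.
* Test problem sizes: survival simulations use n = 2000 where parameter
  recovery is asserted; leakage and null-calibration studies use 50–300
  repeats; end-to-end pipeline tests run a single classifier with reduced
  bootstrap counts. These sizes are the package's choice of
  desk-reproducible defaults; all module defaults remain at the full 2000
  bootstrap / 1000 permutation / 100 stability resamples.

## Known limitations

* The feature inventory is the ~60 features above, not a full PyRadiomics
  parity set; counts of "significant features" are therefore not
  comparable across inventories.
* GLDM uses dependence = 1 + concordant 26-neighbors with α = 0; other
  tools' α conventions differ.
* The mesh surface smooths the indicator before triangulation; sphericity
  of very small ROIs (a few voxels) falls back to the voxel-face
  convention.
* Pooled LOCO AUC is sensitive to cross-center prevalence shifts (above).
* The synthetic generator treats Ki-67 and grade as grade-conditional
  marginals with a median pin; their true joint distribution in any real
  cohort is unknown to it.
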