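---
title: "Quantitative PET mapping and motor-outcome prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative PET mapping and motor-outcome prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmotor)
```

## The scientific problem

Resective surgery for focal cortical dysplasia (FCD) in the Rolandic
cortex — the pre- and postcentral gyri around the central sulcus — trades
seizure freedom against the risk of a permanent motor deficit. Chronic
focal hypometabolism on interictal [18F]FDG-PET marks dysfunctional
cortex; cortex that is still metabolically active presumably still carries
motor function, while long-hypometabolic cortex has often ceded its
function to neighbouring regions (functional reorganization). This package
implements a quantitative pipeline built on that idea:

1. **Normative T-score mapping.** Each subject's PET volume is divided by
   its whole-brain mean uptake, smoothed with an 8 mm FWHM Gaussian, and
   contrasted voxel-by-voxel against a normative control cohort in an
   ordinary-least-squares GLM with age and gender covariates. The result
   is an unthresholded T-score map per patient.
2. **ROI extraction.** The mean T-value inside the intersection of the
   surgical resection mask with the Rolandic atlas labels summarizes how
   metabolically preserved the resected motor cortex was.
3. **Reorganization quantification.** For patients with task fMRI, the
   overlap rate between the binary activation map and the classical motor
   ROI (hand-knob for the upper limb, paracentral lobule for the lower
   limb) measures how far motor function has migrated; it is correlated
   against the classical ROI's mean T.
4. **Outcome model.** A univariate logistic regression predicts
   postoperative motor deficit from the resected-Rolandic mean T, assessed
   by stratified five-fold cross-validation (pooled out-of-fold ROC, AUC,
   sensitivity/specificity at the Youden point) and summarized as an odds
   ratio with a Wald 95% CI.

Because no patient imaging is distributable, the package ships a
first-class synthetic phantom generator with known ground truth; every
claim the pipeline makes is tested against that truth.

## The T-map model

For one patient and $n_c$ controls the per-voxel model is

$$ y_i = \beta_0 + \beta_1 g_i + \beta_2 (a_i - \bar a) + \beta_3 s_i
   + \varepsilon_i, $$

where $y_i$ is normalized smoothed uptake, $g_i$ indicates the patient
(coded 1), $a_i$ is age (centered at the pooled mean) and $s_i \in \{0,1\}$
gender. The reported statistic is $t = \hat\beta_1 / \widehat{\mathrm{se}}
(\hat\beta_1)$ with $n_c + 1 - 4$ degrees of freedom. Conventions:

* **Contrast direction** is patient minus controls, so hypometabolism
  yields negative $t$; "higher T" means closer to normal metabolism.
* **Zero-residual-variance voxels** (possible only in noise-free synthetic
  data) are assigned $t = 0$ and flagged, so region means stay defined.
* **Masking** is strict: no finite $t$ is produced outside the analysis
  mask, and a grid mismatch is a hard error — the package never resamples.
* **Smoothing** uses a separable Gaussian truncated at $4\sigma$ with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in voxel units, and
  mask renormalization (convolved masked image divided by the convolved
  mask). A constant in-mask image is therefore a fixed point — a testable
  invariant that zero-padding convolution lacks. The global-scale
  invariance (multiplying any input volume by $k$ leaves the T-map
  unchanged) follows from the normalization step and is asserted in the
  tests.

No cluster inference or multiple-comparison correction is applied: the
map is consumed unthresholded by the ROI statistics.

## Statistical tests

All reported tests are implemented from first principles and
cross-checked in the test suite against independent implementations:

* **Mann–Whitney U** from midranks; exact two-sided p by enumerating the
  null distribution (dynamic programming over the Gaussian-binomial
  recurrence) when $n_x n_y \le 400$ and no ties are present, otherwise a
  normal approximation with tie and continuity corrections (both
  configurable). Two-sidedness is defined symmetrically,
  $P(|U - \mu| \ge |u - \mu|)$.
* **Kruskal–Wallis** with tie correction against $\chi^2_{k-1}$; an exact
  permutation option enumerates all group assignments for total $n \le 10$.
* **Fisher's exact test** for 2×2 tables with the probability-mass rule:
  the two-sided p sums hypergeometric probabilities of all tables (fixed
  margins) no more probable than the observed one, with a $10^{-12}$
  relative slack. The doubling rule is deliberately not used.
* **Pearson correlation** with the Fisher-z 95% CI and a t-test p-value.
* **Cohort summary** tables report mean ± SD with Mann–Whitney p for
  continuous variables and counts with half-up one-decimal percentages and
  Fisher p for binary variables. Note that half-up rounding of 27/62
  yields 43.5%, and of 35/62 yields 56.5%; a source printing 43.6% and
  56.5% for that split is internally inconsistent (the pair sums past
  100%), so the renderer keeps the rounding rule rather than the printed
  figure.

No multiple-testing correction is applied anywhere, matching the analysis
style the pipeline reproduces.

## Outcome model choices

* The logistic MLE is fit by IRLS (score tolerance $10^{-8}$, 100
  iterations). Complete or quasi-complete separation is detected
  (perfectly classified responses or diverging linear predictors with a
  non-vanishing gradient) and reported as a distinct condition; Wald
  inference is refused on separated fits rather than silently reported.
* **Wald CIs** (not profile likelihood) for the odds ratio, matching the
  symmetric multiplicative CI shape conventionally printed. The OR is
  emitted both per unit T and per SD of T, since odds ratios are
  meaningless without their scale.
* **Stratified five-fold CV**: within each class subjects are shuffled by
  a seeded substream and dealt so per-fold class counts differ from
  proportionality by at most one; remainders go to the least-filled folds,
  keeping fold sizes within one of each other (for 26/36 that gives folds
  of 13, 13, 12, 12, 12 with 5–6 deficit patients each).
* **Pooled CV ROC** (not per-fold averaging), because a single AUC /
  sensitivity / specificity triple is the conventional summary; per-fold
  AUCs are retained as supplementary output. The operating threshold
  maximizes Youden's J on the pooled ROC with ties broken toward higher
  sensitivity, and the fixed-0.5 threshold is reported alongside for
  transparency. AUC uses the rank (Mann–Whitney) formulation with
  midranks, which equals the trapezoidal ROC integral exactly.

## The synthetic phantom

The generator defines the study conditions and is itself tested code.

* **Grid and atlas.** Default 40×48×40 voxels at 2 mm. The atlas places a
  Rolandic strip per hemisphere with the hand-knob (lateral) and
  paracentral lobule (medial) carved out as separate labels, constructed
  in fractional coordinates on the left and mirrored voxel-for-voxel, so
  mirror symmetry is exact by construction. Shapes are boxes intersected
  with an ellipsoidal brain mask — anatomical realism is irrelevant to the
  set arithmetic and statistics under test.
* **Controls** (default 52): uptake = 100 + 0.2·(age − 21.5) + 1·gender +
  N(0, 10) inside the brain, zero outside; ages uniform on [3, 40] years,
  gender Bernoulli(0.5). Only the covariates' role in the design matters,
  so the effects are small but nonzero.
* **Patients** (default 62): an axis-aligned ellipsoidal lesion (semi-axes
  uniform on [4, 9] mm) centred at a random voxel of one side's Rolandic
  area — including the hand-knob and paracentral labels, where Rolandic
  FCD typically sits — with a per-patient fractional uptake reduction
  drawn around `lesion_effect` = 0.3 (SD one third of the mean, truncated
  to [0, 0.95]). The resection is the lesion dilated by one voxel with a
  random 10% of the added shell removed, so it always covers the lesion
  and its Rolandic overlap lands on the cm³ scale of reported resected
  volumes.
* **Ground-truth T.** The generator expresses each patient's expected
  resected-Rolandic mean T analytically: the noise-free normalized,
  smoothed fractional signal change divided by the analytic residual SD of
  a normalized smoothed image, `(noise_sd / baseline) * L2(kernel)`, and
  by `sqrt(1 + 1/n_controls)` (the exact group-contrast factor when
  covariates are orthogonal to group). This first-order truth is what the
  deficit link consumes, so parameter recovery can be checked without
  circularity through the estimation pipeline.
* **Outcome link.** Deficit ~ Bernoulli(plogis(4.01 + 0.29·trueMeanT)).
  The two constants were calibrated once, against the generator's analytic
  truth on a large cohort, so that deficit prevalence is 26/62 and the
  true model's AUC is 0.82 — the operating point the pipeline is meant to
  work at — and then frozen. Strength grades 2/3/4 are assigned by tercile
  of true mean T among deficit patients (highest T, i.e. most preserved
  metabolism in resected cortex, gets the worst grade), making the
  grade-wise trend monotone by construction.
* **Activation maps.** A 3 mm spherical blob at the classical ROI
  centroid, displaced by `reorg_shift_mm` (150 mm per unit) times the mean
  smoothed fractional uptake reduction in that ROI — posterior-inferior
  for hand, anterior for foot. Typical in-ROI deficits of 0.02–0.15 give
  displacements of roughly 3–20 mm, the scale on which reorganization
  shifts are described. Displacements that would push the blob off the
  grid are clamped with a warning (and walked back toward the centroid if
  the clamp would strand the blob outside the brain). All patients get
  activation volumes; the fMRI *analysis subgroup* is the first `n_fmri`
  (default 15) patient ids, mirroring how a study subset arises.

### What the phantom does and does not emulate

It emulates the statistical structure the pipeline depends on: normative
voxel noise, covariate effects, focal multiplicative hypometabolism,
resection/lesion geometry with guaranteed Rolandic overlap, a logistic
outcome link on the region mean T, and metabolism-coupled activation
displacement. It does **not** emulate PET physics (scanner PSF,
attenuation, partial volume), anatomical shapes, spatial normalization
error, or fMRI preprocessing — activation maps enter as binary masks on
the shared grid. Passing tests therefore validate the *estimation
machinery*, not robustness to registration or acquisition artifacts.

## Numerical and design choices

* All randomness flows from one integer seed; per-subject substreams are
  derived by a stable string hash of the subject id, so adding a subject
  never perturbs the others, and identical configurations reproduce
  bit-identical datasets.
* Pipeline stages communicate through files with MD5-checksummed
  manifests; a stage re-executes only when its input signature or outputs
  changed. Volumes are written as uncompressed NIfTI-1 so re-written
  outputs are byte-identical and idempotence is exact (gzip would embed
  metadata). The run manifest carries no timestamps, making "identical
  config, identical manifest" a testable property.
* Degenerate inputs: empty resection∩Rolandic intersections exclude the
  patient with a warning (the study's inclusion criteria guarantee
  nonemptiness in real cohorts); a single-class outcome skips the
  prediction stage with an explicit note in the report; folds are capped
  at the smallest class size.
* The overlap-rate denominator is the activation volume |A| — rate 1 means
  no reorganization, 0 means full displacement. The alternative Dice form
  is exposed behind `rate_type = "dice"` for sensitivity analysis, since
  published overlap rates often leave the denominator implicit.

## Problem sizes used in the test suite

Unit and property tests run on 8³–24×28×24 grids with 4–16 subjects,
chosen so each oracle comparison (normal-equations OLS, permutation
enumeration, brute-force voxel loops) stays exhaustive. Calibration
properties use sample-level simulation (2,000 Mann–Whitney replicates at
26 vs 36; 100 logistic replicates at n = 400) and a reduced-scale
image pipeline (24×28×24, 200 patients × 50 seeds for the null AUC
check). The end-to-end smoke and determinism checks run the full default
phantom (52 controls + 62 patients on 40×48×40), which completes in well
under a minute per run on one CPU.

## Known limitations

* The T-scale ground truth is first-order: it ignores the slight global-
  mean shift a lesion induces in its own normalizer and edge effects of
  mask-renormalized smoothing; both are negligible at the default lesion
  sizes but would bias the "truth" for lesions occupying a large brain
  fraction.
* The per-patient GLM assumes homoscedastic Gaussian voxel noise shared
  with controls; real PET noise is spatially structured.
* Activation "reorganization" is a rigid centroid displacement of a fixed
  blob, not a reshaping of activation topology.
* The atlas phantom's label geometry is schematic; results about overlap
  *statistics* transfer to real atlases, results about absolute overlap
  values do not.
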